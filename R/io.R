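# Count-table and coverage-config I/O, plus the synthetic fixture generator.
#
# Count tables are tab-separated: a header row of sample IDs, first column
# of gene IDs, integer cells. The coverage config is YAML, one entry per
# sample; each sample either states its coverage directly or supplies the
# quantities it is derived from (total reads plus one of: a fragment
# population size, a loading concentration/volume, or a post-PCR fragment
# yield with a cycle count), optionally with a PCR efficiency.

# Validate/convert counts input into an integer matrix with gene row names.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    if (ncol(counts) >= 1L && (is.character(counts[[1L]]) ||
                               is.factor(counts[[1L]]))) {
      ids <- as.character(counts[[1L]])
      counts <- as.matrix(counts[, -1L, drop = FALSE])
      rownames(counts) <- ids
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix or a data frame of counts")
  if (nrow(counts) > 0L && is.null(rownames(counts)))
    stop("'counts' must carry gene IDs (row names or a first ID column)")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicated gene ID(s): %s",
                 paste(utils::head(unique(rownames(counts)[duplicated(rownames(counts))]), 5),
                       collapse = ", ")))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample IDs in the count table")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "count table cells must be non-negative integers; first offender: gene '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
      format(counts[bad[1L, , drop = FALSE]])))
  storage.mode(counts) <- "integer"
  counts
}

#' Read a gene-count table
#'
#' Reads a tab-separated count table (header row of sample IDs, first column
#' of gene IDs) and validates it: all cells must be non-negative integers,
#' rows must not be ragged, and gene/sample IDs must be unique. Errors name
#' the offending line or cell.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix, genes x samples, with gene IDs as row names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path))
    stop(sprintf("count file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop(sprintf("'%s': need a header line and at least one gene row", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_samples <- length(header) - 1L
  if (n_samples < 1L)
    stop(sprintf("'%s': header must list at least one sample", path))
  samples <- header[-1L]
  widths <- lengths(cells[-1L])
  if (any(widths != n_samples + 1L)) {
    bad <- which(widths != n_samples + 1L)[1L] + 1L
    stop(sprintf("'%s': line %d has %d fields, expected %d", path, bad,
                 length(cells[[bad]]), n_samples + 1L))
  }
  ids <- vapply(cells[-1L], `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(cells[-1L], function(r) as.numeric(r[-1L]), numeric(n_samples)))
  vals <- matrix(vals, ncol = n_samples, byrow = TRUE,
                 dimnames = list(ids, samples))
  nonnum <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nonnum))
    stop(sprintf("'%s': line %d, sample '%s': not a number", path,
                 nonnum[1L, 1L] + 1L, samples[nonnum[1L, 2L]]))
  as_count_matrix(vals)
}

#' Write a gene-count table
#'
#' Inverse of [read_counts()]: writes a TSV with a `gene_id` header column.
#'
#' @param counts Count matrix or data frame accepted by [call_table()].
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  cm <- as_count_matrix(counts)
  df <- data.frame(gene_id = rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a DEG call table
#'
#' @param calls Data frame of per-gene calls ([call_table()] output or the
#'   `calls` component of a [cornas()] fit).
#' @param path Output path.
#' @export
write_deg_table <- function(calls, path) {
  if (inherits(calls, "cornas")) calls <- calls$calls
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample coverages from a YAML config
#'
#' Each entry of the `samples` mapping (or each top-level entry) describes
#' one sample by any of:
#' \itemize{
#'   \item `coverage`: the coverage directly;
#'   \item `total_reads` (plus optional `end_mode`, `"single"` or
#'     `"paired"`; paired reads are halved to fragment counts; several
#'     sequencing runs may be given as a vector, which is averaged) together
#'     with one of `fragments_N`, (`concentration_pM`, `volume_uL`), or
#'     (`post_pcr_fragments`, `cycles`); when none is given the standard
#'     3e8 fragment population is assumed;
#'   \item optional `pcr_efficiency` (and `pcr_cycles`), applied as a
#'     retention correction to the fragment population.
#' }
#'
#' @param path Path to the YAML file.
#' @return Named numeric vector of coverages, with a `details` attribute
#'   holding a per-sample data frame of the derived quantities.
#' @export
read_coverage_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("coverage config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$samples)) cfg <- cfg$samples
  if (!length(cfg) || is.null(names(cfg)) || any(!nzchar(names(cfg))))
    stop(sprintf("'%s': expected a named mapping of samples", path))
  rows <- lapply(names(cfg), function(id) {
    entry <- cfg[[id]]
    tryCatch(coverage_from_config(id, entry),
             error = function(e) stop(sprintf(
               "sample '%s': %s", id, conditionMessage(e)), call. = FALSE))
  })
  details <- do.call(rbind, rows)
  out <- details$coverage
  names(out) <- details$sample_id
  attr(out, "details") <- details
  out
}

coverage_from_config <- function(id, entry) {
  if (!is.list(entry))
    stop("entry must be a mapping")
  eff <- entry$pcr_efficiency %||% 1
  cycles <- entry$pcr_cycles %||% DEFAULT_PCR_CYCLES
  if (!is.null(entry$coverage)) {
    b <- entry$coverage
    check_coverage(b, "coverage")
    S <- NA_real_; N <- NA_real_
  } else {
    if (is.null(entry$total_reads))
      stop("needs either 'coverage' or 'total_reads'")
    reads <- mean(as.numeric(entry$total_reads))  # average over runs
    end_mode <- entry$end_mode %||% "single"
    if (!end_mode %in% c("single", "paired"))
      stop("'end_mode' must be 'single' or 'paired'")
    S <- if (end_mode == "paired") reads / 2 else reads
    if (!is.null(entry$fragments_N)) {
      N <- as.numeric(entry$fragments_N)
    } else if (!is.null(entry$concentration_pM)) {
      N <- fragments_from_concentration(as.numeric(entry$concentration_pM),
                                        as.numeric(entry$volume_uL %||% 120))
    } else if (!is.null(entry$post_pcr_fragments)) {
      N <- prepcr_fragments(as.numeric(entry$post_pcr_fragments), cycles)
    } else {
      N <- DEFAULT_FRAGMENT_POPULATION
    }
    b <- adjusted_coverage(S, N, efficiency = eff, cycles = cycles)
  }
  data.frame(sample_id = id, coverage = b, reads_S = S, fragments_N = N,
             pcr_efficiency = eff, pcr_cycles = cycles,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic two-sample count table with known truth
#'
#' Builds a fixture through the same fragment-sampling mechanism the count
#' model assumes: true counts are drawn log-uniformly over
#' `true_count_range`, a subset of genes is differentially expressed (half
#' up, half down, their treatment true counts scaled by `fold` or `1/fold`),
#' and observed counts are drawn hypergeometrically at the stated coverages.
#' Fully deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param n_deg Number of truly differentially expressed genes.
#' @param fold True fold change applied to DE genes (> 1).
#' @param coverage Length-2 vector of (control, treatment) coverages.
#' @param seed Integer seed (required; recorded in the output).
#' @param population_N Fragment population size (default 3e6).
#' @param true_count_range Range of control-sample true counts (default
#'   10 to 10,000).
#' @param dir Optional directory; when given, `counts.tsv` and `truth.tsv`
#'   are written there.
#' @return List with `counts` (integer matrix, samples `control` and
#'   `treatment`), `truth` (data frame `gene_id`, `direction`, plus the true
#'   counts), `coverage`, and `seed`. If `dir` is given, also `paths`.
#' @examples
#' fx <- make_fixture(n_genes = 20, n_deg = 4, fold = 4,
#'                    coverage = c(0.25, 0.25), seed = 1)
#' head(fx$truth)
#' @export
make_fixture <- function(n_genes, n_deg, fold, coverage, seed,
                         population_N = 3e6,
                         true_count_range = c(10, 10000), dir = NULL) {
  if (n_deg > n_genes) stop("'n_deg' must not exceed 'n_genes'")
  if (fold <= 1) stop("'fold' must exceed 1")
  check_coverage(coverage[[1L]], "coverage[control]")
  check_coverage(coverage[[2L]], "coverage[treatment]")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      seed != round(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- sprintf("gene%04d", seq_len(n_genes))
  k_control <- round(exp(stats::runif(n_genes, log(true_count_range[1L]),
                                      log(true_count_range[2L]))))
  deg_idx <- sample.int(n_genes, n_deg)
  up <- deg_idx[seq_len(ceiling(n_deg / 2))]
  down <- setdiff(deg_idx, up)
  k_treatment <- k_control
  k_treatment[up] <- round(fold * k_control[up])
  k_treatment[down] <- pmax(1L, round(k_control[down] / fold))

  S0 <- round(coverage[[1L]] * population_N)
  S1 <- round(coverage[[2L]] * population_N)
  counts <- cbind(
    control = sample_observed_count(k_control, S0, population_N),
    treatment = sample_observed_count(k_treatment, S1, population_N))
  rownames(counts) <- ids

  direction <- rep("none", n_genes)
  direction[up] <- "up"
  direction[down] <- "down"
  truth <- data.frame(gene_id = ids, direction = direction,
                      k_control = k_control, k_treatment = k_treatment,
                      stringsAsFactors = FALSE)
  truth <- truth[truth$direction != "none", , drop = FALSE]

  out <- list(counts = counts, truth = truth,
              coverage = c(control = coverage[[1L]],
                           treatment = coverage[[2L]]),
              seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(counts = file.path(dir, "counts.tsv"),
               truth = file.path(dir, "truth.tsv"))
    write_counts(counts, paths[["counts"]])
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
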