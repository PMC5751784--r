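test_that("identical samples are never called", {
  for (x in c(0, 3, 100, 5000)) {
    cl <- call_gene(x, 0.25, x, 0.25, alpha = 0.99, phi = 1)
    expect_equal(cl$direction, "none")
    # equal posteriors: the 0.5th percentile sits below the 99.5th
    expect_lt(cl$fold_bound, 1)
  }
})

test_that("a clear fold change is called with the frozen fold bound", {
  cl <- call_gene(100, 0.25, 1000, 0.25)
  expect_equal(cl$direction, "up")
  # frozen via an independent gamma-quantile implementation
  expect_equal(cl$fold_bound, 7.62798269342165, tolerance = 1e-10)
  expect_equal(cl$joint_credibility, 0.995^2)
  rev <- call_gene(1000, 0.25, 100, 0.25)
  expect_equal(rev$direction, "down")
  expect_equal(rev$fold_bound, cl$fold_bound)
})

test_that("direction reflects which sample has the larger posterior mean", {
  up <- call_gene(50, 0.25, 400, 0.25)
  expect_equal(up$direction, "up")
  expect_gt(up$mean_treatment, up$mean_control)
  down <- call_gene(400, 0.25, 50, 0.25)
  expect_equal(down$direction, "down")
  expect_lt(down$mean_treatment, down$mean_control)
})

test_that("call_table preserves order and validates its inputs", {
  calls <- call_table(toy_counts(), "ctl", "trt", c(ctl = 0.25, trt = 0.25))
  expect_equal(calls$gene_id, c("gUp", "gDown", "gFlat"))
  expect_equal(calls$direction, c("up", "down", "none"))
  # matches the scalar path gene by gene
  for (i in 1:3) {
    one <- call_gene(toy_counts()[i, "ctl"], 0.25, toy_counts()[i, "trt"], 0.25)
    expect_equal(calls$fold_bound[i], one$fold_bound)
  }
  expect_error(call_table(toy_counts(), "ctl", "nope", c(ctl = 0.25, nope = 0.25)),
               "sample 'nope' not found")
  dup <- toy_counts()
  rownames(dup) <- c("g", "g", "h")
  expect_error(call_table(dup, "ctl", "trt", c(ctl = 0.25, trt = 0.25)),
               "duplicated gene")
  neg <- toy_counts()
  neg[2, 1] <- -3L
  expect_error(call_table(neg, "ctl", "trt", c(ctl = 0.25, trt = 0.25)),
               "gene 'gDown', sample 'ctl'")
  frac <- matrix(c(1.5, 2), nrow = 1,
                 dimnames = list("g1", c("ctl", "trt")))
  expect_error(call_table(frac, "ctl", "trt", c(ctl = 0.25, trt = 0.25)),
               "non-negative integers")
  empty <- matrix(integer(0), nrow = 0, ncol = 2,
                  dimnames = list(character(0), c("ctl", "trt")))
  expect_equal(nrow(call_table(empty, "ctl", "trt", c(ctl = 0.25, trt = 0.25))), 0)
})

test_that("the DEG set shrinks as phi or alpha grows", {
  fx <- make_fixture(n_genes = 150, n_deg = 30, fold = 2,
                     coverage = c(0.25, 0.25), seed = 11)
  deg_set <- function(alpha, phi) {
    calls <- call_table(fx$counts, "control", "treatment", fx$coverage,
                        alpha = alpha, phi = phi)
    calls$gene_id[calls$direction != "none"]
  }
  s_phi <- lapply(c(1, 1.5, 2), function(phi) deg_set(0.99, phi))
  expect_true(all(s_phi[[2]] %in% s_phi[[1]]))
  expect_true(all(s_phi[[3]] %in% s_phi[[2]]))
  expect_gt(length(s_phi[[1]]), length(s_phi[[3]]))
  s_alpha <- lapply(c(0.8, 0.95, 0.999), function(a) deg_set(a, 1.5))
  expect_true(all(s_alpha[[2]] %in% s_alpha[[1]]))
  expect_true(all(s_alpha[[3]] %in% s_alpha[[2]]))
})

test_that("swapping the samples flips up and down calls", {
  fx <- make_fixture(n_genes = 80, n_deg = 20, fold = 3,
                     coverage = c(0.25, 0.1), seed = 5)
  fwd <- call_table(fx$counts, "control", "treatment",
                    c(control = 0.25, treatment = 0.1))
  swapped <- call_table(fx$counts, "treatment", "control",
                        c(control = 0.25, treatment = 0.1))
  flip <- c(up = "down", down = "up", none = "none")
  expect_equal(swapped$direction, unname(flip[fwd$direction]))
  expect_equal(swapped$fold_bound, fwd$fold_bound)
})

test_that("larger counts at fixed coverage sharpen a borderline fold change", {
  # true 2-fold difference: at small counts the intervals are too wide to
  # call, at large counts the relative intervals tighten and the call appears
  b <- 0.25
  fold_bounds <- vapply(c(10, 100, 1000, 10000), function(x0)
    call_gene(x0, b, 2 * x0, b)$fold_bound, numeric(1))
  expect_true(all(diff(fold_bounds) > 0))
  expect_lt(fold_bounds[1], 1.5)
  expect_gte(fold_bounds[4], 1.5)
})

test_that("the cornas fit object carries calls, parameters and methods", {
  fx <- make_fixture(n_genes = 60, n_deg = 10, fold = 4,
                     coverage = c(0.25, 0.25), seed = 7)
  fit <- cornas(fx$counts, "control", "treatment", fx$coverage)
  expect_s3_class(fit, "cornas")
  expect_equal(nrow(fit$calls), 60)
  expect_equal(fit$alpha, 0.99)
  expect_equal(fit$phi, 1.5)
  expect_equal(fit$joint_credibility, 0.995^2)
  expect_output(print(fit), "up, \\d+ down")
  expect_output(print(summary(fit)), "Strongest calls")
  cf <- coef(fit)
  expect_equal(dim(cf), c(60, 2))
  expect_equal(rownames(cf), rownames(fx$counts))
  expect_equal(as.data.frame(fit), fit$calls)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("out-of-range coverage is rejected with the usage caveat", {
  expect_error(call_gene(10, 1.2, 20, 0.25), "not recommended")
  expect_error(call_gene(10, 0.25, 20, 0), "coverage")
  expect_error(cornas(toy_counts(), "ctl", "trt", c(ctl = 0.25, trt = 1)),
               "coverage")
})
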