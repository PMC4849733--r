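# shared generators for the test suite; everything is built in code at
# test time under fixed seeds

random_dataset <- function(J, seed, slope = 0.1, pleio_sd = 0,
                           signed = TRUE) {
  set.seed(seed)
  gx <- stats::runif(J, 0.03, 0.2)
  if (signed) gx <- gx * sample(c(-1, 1), J, replace = TRUE)
  se_x <- stats::runif(J, 0.005, 0.02)
  se_y <- stats::runif(J, 0.003, 0.02)
  gy <- slope * gx + stats::rnorm(J, sd = pleio_sd * abs(gx)) +
    stats::rnorm(J, sd = se_y)
  mr_data(sprintf("rs%03d", seq_len(J)), beta_exposure = gx,
          se_exposure = se_x, beta_outcome = gy, se_outcome = se_y)
}

# mr_ratios constructor honouring the sorted-ascending invariant
make_ratios <- function(beta, weight, scheme = "inverse_variance") {
  o <- order(beta)
  structure(list(beta = beta[o], weight = weight[o],
                 variant_id = sprintf("v%03d", seq_along(beta))[o],
                 weight_scheme = scheme),
            class = "mr_ratios")
}

# brute-force pseudopopulation median: round(copies * w_j) copies of each
# ordered ratio estimate
pseudo_median <- function(beta, w, copies = 1e6) {
  stats::median(rep(beta, round(copies * w / sum(w))))
}

table1_weights <- list(
  equal = rep(1, 10),
  weighting1 = c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1),
  weighting2 = c(2, 3, 10, 8, 5, 3, 2, 1, 1, 1))

percentiles_of <- function(w, beta = seq_along(w)) {
  build_weighted_cdf(make_ratios(beta, w))$p
}
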