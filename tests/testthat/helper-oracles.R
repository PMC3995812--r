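# Independent oracles used across tests.

# Brute-force maximization of the single-covariate Cox partial likelihood
# (no ties) on a grid; deliberately naive and independent of survival::coxph.
grid_cox_beta <- function(time, event, x, betas = seq(-5, 5, by = 1e-4)) {
  loglik <- vapply(betas, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }, numeric(1))
  list(beta = betas[which.max(loglik)], interior = {
    j <- which.max(loglik); j > 1 && j < length(betas)
  })
}

# Hand computation of the 2-group log-rank statistic (sum of observed minus
# hypergeometric-expected events in group 1, squared over the variance).
hand_logrank_chisq <- function(time, event, group1) {
  dt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Tiny disease-free-survival data.frame constructor for toy cases.
toy_cohort <- function(time, event, ..., id = seq_along(time)) {
  data.frame(patient_id = as.character(id), time_to_recurrence = time,
             event = event, ..., stringsAsFactors = FALSE)
}

tile_center <- function(config = image_sim_config()) {
  c((config$tile_height - 1) / 2, (config$tile_width - 1) / 2)
}
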