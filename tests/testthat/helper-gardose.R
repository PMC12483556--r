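# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the packaged signature file.

# small uncensored toy: two clearly separated survival groups
toy_two_groups <- function() {
  list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
       group = c("A", "A", "B", "B"))
}

# 5-record single-covariate fixture without ties (Cox grid oracle)
toy_cox_fixture <- function() {
  data.frame(
    time_months = c(2, 5, 7, 11, 16),
    event = c(1, 1, 0, 1, 1),
    x = c(1.1, -0.4, 0.8, -1.2, 0.3)
  )
}

# brute-force Cox partial likelihood (Breslow form; fixture has no ties)
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# expression matrix over the signature genes
toy_expression <- function(n_samples = 4, seed = 1, genes = rsi_signature()$gene) {
  set.seed(seed)
  matrix(rnorm(length(genes) * n_samples, mean = 8, sd = 2),
         nrow = length(genes),
         dimnames = list(genes, paste0("S", seq_len(n_samples))))
}

# plain pair-counting AUC for uncensored case/control data
paircount_auc <- function(marker_case, marker_ctrl) {
  s <- 0
  for (a in marker_case) {
    s <- s + sum(a > marker_ctrl) + 0.5 * sum(a == marker_ctrl)
  }
  s / (length(marker_case) * length(marker_ctrl))
}

default_dist <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_rsi_distribution()
    cache
  }
})
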