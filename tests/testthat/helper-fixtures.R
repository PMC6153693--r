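# Shared fixtures: a canonical aggregate model and grid used across tests.

default_test_grid <- function(n = 200) q_log_grid(1e-3, 1e2, n)

floc_model <- function(Df = 2.2, Rg = 100, Rp = 0.5, a = 20) {
  aggregate_model(Rg = Rg, Rp = Rp, a = a, Df = Df)
}

# Independent closed-form OLS on (x, y): the oracle against which the
# package's fitting path is checked.
ols_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept,
       stderr = sqrt(rss / (n - 2) / sxx),
       r2 = 1 - rss / sum((y - my)^2))
}
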