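# Independent oracles used across tests. These deliberately avoid lm() and
# the package's own fitting path.

# Simple-regression normal equations, written out longhand.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta1 <- sxy / sxx
  beta0 <- mean(y) - beta1 * mean(x)
  fitted <- beta0 + beta1 * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta0 = beta0, beta1 = beta1,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       sigma2 = ss_res / (n - 2))
}

# Externally studentized residual for point i by literally refitting
# without it: t_i = e_i / (s_(i) * sqrt(1 - h_i)).
loo_studentized_oracle <- function(x, y) {
  full <- ols_oracle(x, y)
  n <- length(x)
  h <- 1 / n + (x - mean(x))^2 / sum((x - mean(x))^2)
  e <- y - (full$beta0 + full$beta1 * x)
  vapply(seq_len(n), function(i) {
    drop_fit <- ols_oracle(x[-i], y[-i])
    e[i] / (sqrt(drop_fit$sigma2) * sqrt(1 - h[i]))
  }, numeric(1))
}

# A small clean synthetic regression data set on the transformed scale.
make_points <- function(n, beta0 = 5.611, beta1 = -5.742, sd = 0.15,
                        seed = 1, x_range = c(0.01, 0.4)) {
  set.seed(seed)
  x <- seq(x_range[1], x_range[2], length.out = n)
  data.frame(year = 1969 + seq_len(n), x = x,
             y = beta0 + beta1 * x + rnorm(n, 0, sd))
}

# A small observed-scale series with linear motorization growth.
make_series <- function(years = 2000:2009, x = seq(0.05, 0.32, length.out = 10),
                        params = smeed_params(a = 273.42, b = 5.742),
                        population = 1e7, country = "Demo") {
  mortality <- predict_mortality(params, x)
  country_series(country, data.frame(
    year = years, deaths = mortality * population / 1e5,
    vehicles = x * population, population = population))
}
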