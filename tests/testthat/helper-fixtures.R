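# Shared fixtures: small datasets built in code.

# tiny p-feature dataset with a generic schema
toy_dataset <- function(n = 60, p = 4, seed = 1, separable = FALSE) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  if (separable) X[, 1] <- ifelse(y == 1, X[, 1] + 10, X[, 1] - 10)
  sch <- data.frame(index = seq_len(p) - 1L, name = paste0("x", seq_len(p) - 1L),
                    kind = "continuous", description = "")
  gs_dataset(X, y, sch)
}

# XOR-structured 2-feature data: no depth-1 tree can separate it
xor_dataset <- function(n = 120, seed = 1) {
  set.seed(seed)
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  X <- cbind(a + rnorm(n, sd = 0.05), b + rnorm(n, sd = 0.05))
  sch <- data.frame(index = 0:1, name = c("x0", "x1"), kind = "continuous",
                    description = "")
  gs_dataset(X, as.integer(xor(a == 1, b == 1)), sch)
}

# plain-function model exposing a probability: threshold on one feature
threshold_model <- function(col = 1L, cut = 5) {
  function(X) as.numeric(X[, col] > cut)
}

extdata <- function(f) system.file("extdata", f, package = "scsorf")

# independent MAD scale (mirrors the package convention: zero MADs -> 1)
mad_scale_for_test <- function(X) {
  s <- apply(as.matrix(X), 2, mad)
  s[s == 0] <- 1
  s
}

# Independent Shapley oracle: average marginal contribution over every
# ordering, with coalition values computed by direct background overwrite.
oracle_value <- function(model, x, subset, background) {
  bg <- as.matrix(background)
  if (length(subset)) {
    cols <- subset + 1L
    bg[, cols] <- matrix(x[cols], nrow(bg), length(cols), byrow = TRUE)
  }
  mean(predict_prob(model, bg))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

oracle_shapley <- function(model, x, background, features) {
  g <- length(features)
  perms <- all_perms(g)
  phi <- numeric(g)
  for (p in seq_len(nrow(perms))) {
    run <- integer(0)
    v_prev <- oracle_value(model, x, integer(0), background)
    for (j in perms[p, ]) {
      run <- c(run, features[j])
      v_new <- oracle_value(model, x, run, background)
      phi[j] <- phi[j] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / nrow(perms)
}
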