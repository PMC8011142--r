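# Programmatic fixtures shared across test files.

# a bout of i.i.d. Gaussian samples around a tilted gravity vector
random_bout <- function(n = 40L, fs = 10.54, seed = 1L, label = "x") {
  set.seed(seed)
  s <- cbind(x = rnorm(n, 0.3, 0.4), y = rnorm(n, 0.0, 0.3),
             z = rnorm(n, 0.9, 0.5))
  acc_bout(s, fs = fs, label = label)
}

# constant-gravity bout (pure posture, no movement)
constant_bout <- function(g = c(0, 0, 1), n = 20L, fs = 10) {
  acc_bout(matrix(rep(g, each = n), n, 3L), fs = fs)
}

# small two-class linearly separable feature table
separable_xy <- function(n_per = 30L, seed = 42L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 3, 0, 0.5), n_per, 3L),
             matrix(rnorm(n_per * 3, 5, 0.5), n_per, 3L))
  colnames(X) <- c("f1", "f2", "f3")
  list(X = X, y = rep(c("alpha", "beta"), each = n_per))
}
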