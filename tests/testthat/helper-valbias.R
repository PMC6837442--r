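# shared fixtures, all built in code

# two well-separated 2-D blobs (linearly separable)
separable_dataset <- function(n = 40, gap = 6, seed = 99) {
  x <- withr::with_seed(seed, matrix(rnorm(n * 2, sd = 0.5), n, 2))
  labels <- rep(c(1L, 0L), each = n / 2)
  x[labels == 1L, 1] <- x[labels == 1L, 1] + gap
  valbias:::new_dataset(x, labels, list(generator = "blobs", seed = seed))
}

# XOR arrangement: no linear separator classifies more than 3 of 4 points
xor_data <- function() {
  list(x = matrix(c(0, 1, 0, 1,
                    0, 1, 1, 0), 4, 2,
                  dimnames = list(NULL, c("f1", "f2"))),
       y = c(1L, 1L, 0L, 0L))
}

# binomial SE (in accuracy percentage points) of a mean over `runs` runs
# with `n_eval` evaluated samples each, at the 50% chance level
chance_se <- function(n_eval, runs) sqrt(50 * 50 / (n_eval * runs))
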