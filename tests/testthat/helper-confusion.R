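# The two published-style confusion matrices used as metric oracles:
# rows are predicted classes, columns actual.
numeric_cm <- function() {
  m <- matrix(0L, 7L, 7L)
  diag(m) <- c(23L, 109L, 18L, 23L, 19L, 2L, 32L)
  m[4L, 2L] <- 3L   # toilet instances predicted as shower
  m[5L, 3L] <- 1L; m[6L, 3L] <- 1L
  m[3L, 5L] <- 1L
  m[3L, 6L] <- 8L
  cls <- c("Bed", "Toilet", "Breakfast", "Shower", "Drink", "Dinner", "Leave")
  dimnames(m) <- list(predicted = cls, actual = cls)
  m
}

binary_cm <- function() {
  m <- matrix(0L, 7L, 7L)
  diag(m) <- c(23L, 112L, 17L, 22L, 20L, 8L, 32L)
  m[2L, 4L] <- 1L
  m[6L, 3L] <- 3L
  m[3L, 6L] <- 2L
  cls <- c("Bed", "Toilet", "Breakfast", "Shower", "Drink", "Dinner", "Leave")
  dimnames(m) <- list(predicted = cls, actual = cls)
  m
}

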