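# Small multi-subject labeled feature set for cross-validation tests:
# Gaussian class centres plus a per-subject offset, cheap enough for full
# CV sweeps inside the unit tests.
synthetic_cv_fixture <- function(n_subjects = 12, n_classes = 3, per = 2,
                                 dim = 5, sep = 4, seed = 1) {
  set.seed(seed)
  centres <- matrix(rnorm(n_classes * dim, sd = sep), n_classes, dim)
  x <- NULL; labels <- integer(0); subjects <- integer(0)
  for (s in seq_len(n_subjects)) {
    soff <- rnorm(dim, sd = 0.5)
    for (cl in seq_len(n_classes)) {
      pts <- matrix(rnorm(per * dim, sd = 0.6), per, dim) +
        matrix(centres[cl, ] + soff, per, dim, byrow = TRUE)
      x <- rbind(x, pts)
      labels <- c(labels, rep(cl, per))
      subjects <- c(subjects, rep(s, per))
    }
  }
  list(x = x, labels = labels, subjects = subjects)
}
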