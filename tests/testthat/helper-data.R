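# Small shared fixtures built in code.

extfile <- function(...) system.file("extdata", ..., package = "lymphcascade")

# tiny two-entity cohort with clean separation, used for fast cascade tests
tiny_cohort <- function(seed = 42, n = 6, shift = 3) {
  set.seed(seed)
  genes <- c(paste0("A", 1:4), paste0("B", 1:4), paste0("N", 1:4))
  labels <- c(rep("entA", n), rep("entB", n), rep("control", n))
  v <- matrix(rnorm(length(genes) * 3 * n, mean = 6, sd = 0.4),
              length(genes), 3 * n,
              dimnames = list(genes, sprintf("t%02d", seq_len(3 * n))))
  v[paste0("A", 1:4), labels == "entA"] <-
    v[paste0("A", 1:4), labels == "entA"] + shift
  v[paste0("B", 1:4), labels == "entB"] <-
    v[paste0("B", 1:4), labels == "entB"] + shift
  list(values = v, labels = labels)
}

# a small fitted cascade on the tiny cohort
tiny_model <- function(seed = 42, ...) {
  tc <- tiny_cohort(seed)
  fit_cascade(tc$values, tc$labels, k = 4, ntree = 100, seed = seed, ...)
}
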