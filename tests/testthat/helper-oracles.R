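# Independent oracles and small fixture builders used across test files.

# Psychometric table straight from proportions (bypasses aggregate_records).
make_ptable <- function(p, n = 40, cl = seq(20, 140, 15), standard = 80,
                        orders = c("sc", "cs")) {
  stopifnot(length(p) == length(cl))
  df <- data.frame(order = rep(orders, each = length(cl)),
                   comparison = rep(cl, length(orders)),
                   n_trials = n,
                   n_c_longer = rep(round(p * n), length(orders)),
                   stringsAsFactors = FALSE)
  structure(df, standard = standard,
            class = c("psychometric_table", "data.frame"))
}

# Brute-force weighted isotonic regression: enumerate all partitions of the
# grid into contiguous blocks, set each block to its weighted mean, keep the
# feasible (non-decreasing) fit with least weighted squared error.
brute_force_isotonic <- function(p, w = rep(1, length(p))) {
  n <- length(p)
  best <- NULL
  best_err <- Inf
  # each composition encoded by the n-1 "cut here" booleans
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    block_id <- cumsum(c(TRUE, cuts))
    vals <- tapply(p * w, block_id, sum) / tapply(w, block_id, sum)
    if (is.unsorted(vals)) next
    fit <- vals[block_id]
    err <- sum(w * (p - fit)^2)
    if (err < best_err - 1e-12) {
      best_err <- err
      best <- as.numeric(fit)
    }
  }
  best
}

# aov()-based oracle for the two-way fully-within ANOVA (subjects x A x B).
oracle_rm_2way <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  df <- expand.grid(S = factor(seq_len(n)), A = factor(seq_len(a)),
                    B = factor(seq_len(b)))
  df$y <- as.vector(y)
  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = df)
  sm <- summary(fit)
  get_f <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(A = get_f("Error: S:A", "A"), B = get_f("Error: S:B", "B"),
    AB = get_f("Error: S:A:B", "A:B"))
}

# aov()-based oracle for the three-way split-plot ANOVA.
oracle_mixed_3way <- function(data) {
  data$subject <- factor(data$subject)
  data$duration <- factor(data$duration)
  data$isi <- factor(data$isi)
  data$stimulus_type <- factor(data$stimulus_type)
  fit <- stats::aov(y ~ duration * isi * stimulus_type + Error(subject / duration),
                    data = data)
  sm <- summary(fit)
  btab <- sm[["Error: subject"]][[1]]
  wtab <- sm[["Error: subject:duration"]][[1]]
  pick <- function(tab, term) tab[trimws(rownames(tab)) == term, "F value"]
  c(isi = pick(btab, "isi"), stimulus_type = pick(btab, "stimulus_type"),
    `isi:stimulus_type` = pick(btab, "isi:stimulus_type"),
    duration = pick(wtab, "duration"),
    `duration:isi` = pick(wtab, "duration:isi"),
    `duration:stimulus_type` = pick(wtab, "duration:stimulus_type"),
    `duration:isi:stimulus_type` = pick(wtab, "duration:isi:stimulus_type"))
}
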