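#' Preset comparison grids
#'
#' The two duration regimes use nine comparison levels symmetric around the
#' standard: 20-140 ms in steps of 15 ms for the 80 ms standard, and
#' 300-700 ms in steps of 50 ms for the 500 ms standard. Both grids contain
#' the standard as their middle (5th) element. Other standards have no
#' preset; pass an explicit grid to [constant_stimuli_design()] instead.
#'
#' @param standard Standard duration in ms (80 or 500 for presets).
#' @return Numeric vector of nine comparison durations (ms).
#' @export
c_grid <- function(standard) {
  if (isTRUE(standard == 80)) return(seq(20, 140, by = 15))
  if (isTRUE(standard == 500)) return(seq(300, 700, by = 50))
  stop("c_grid: no preset grid for standard = ", standard,
       "; supply c_levels explicitly")
}

#' Constant-stimuli design specification
#'
#' One regime of a two-interval constant-stimuli session: every block crosses
#' the comparison levels with the two stimulus orders, repeats each of the
#' resulting trial types `reps_per_block` times, and shuffles the block.
#' The preset (9 levels x 2 orders x 2 reps x 20 blocks) yields 18 trial
#' types, 36 trials per block and 720 trials.
#'
#' @param standard Standard duration (ms).
#' @param c_levels Comparison grid, symmetric around the standard.
#' @param reps_per_block Repetitions of each trial type per block.
#' @param n_blocks Number of blocks.
#' @param isi Inter-stimulus interval label in ms (presets use 200 or 900).
#' @param stimulus_type `"filled"` or `"empty"`; a pure label for the
#'   simulator.
#' @param seed Optional integer; if given, [build_design()] shuffles with an
#'   isolated RNG stream seeded from it.
#' @return A `constant_stimuli_design`.
#' @export
constant_stimuli_design <- function(standard, c_levels = c_grid(standard),
                                    reps_per_block = 2, n_blocks = 20,
                                    isi = 900,
                                    stimulus_type = c("filled", "empty"),
                                    seed = NULL) {
  stimulus_type <- match.arg(stimulus_type)
  stopifnot(is.numeric(standard), length(standard) == 1L, standard > 0,
            is.numeric(c_levels), length(c_levels) >= 1L,
            reps_per_block >= 1, n_blocks >= 1)
  c_levels <- sort(c_levels)
  if (any(abs(c_levels + rev(c_levels) - 2 * standard) > 1e-8)) {
    stop("constant_stimuli_design: c_levels must be symmetric around the standard")
  }
  structure(list(standard = standard, c_levels = c_levels,
                 reps_per_block = as.integer(reps_per_block),
                 n_blocks = as.integer(n_blocks), isi = isi,
                 stimulus_type = stimulus_type, seed = seed),
            class = "constant_stimuli_design")
}

# Evaluate `code` under an isolated RNG stream seeded with `seed`,
# restoring the ambient stream afterwards. NULL seed = use ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Expand a design into a randomized trial sequence
#'
#' Crosses comparison levels with stimulus orders into trial types, repeats
#' each type `reps_per_block` times and shuffles independently within every
#' block, so that stimulus order varies randomly from trial to trial. The
#' output is a data frame of trial specifications in presentation order; the
#' multiset of trial types per block is deterministic, only their order
#' depends on the seed.
#'
#' @param design A [constant_stimuli_design()].
#' @return Data frame with columns `block`, `trial_in_block`, `order`
#'   (`"sc"`/`"cs"`), `standard`, `comparison`, `first_duration`,
#'   `second_duration`, `isi`, `stimulus_type`.
#' @export
build_design <- function(design) {
  stopifnot(inherits(design, "constant_stimuli_design"))
  types <- expand.grid(comparison = design$c_levels, order = c("sc", "cs"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  block_rows <- types[rep(seq_len(nrow(types)), times = design$reps_per_block), ]
  m <- nrow(block_rows)
  with_seed(design$seed, {
    blocks <- lapply(seq_len(design$n_blocks), function(b) {
      shuffled <- block_rows[sample.int(m), ]
      data.frame(block = b, trial_in_block = seq_len(m),
                 order = shuffled$order,
                 standard = design$standard,
                 comparison = shuffled$comparison,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    out$first_duration <- ifelse(out$order == "sc", out$standard, out$comparison)
    out$second_duration <- ifelse(out$order == "sc", out$comparison, out$standard)
    out$isi <- design$isi
    out$stimulus_type <- design$stimulus_type
    rownames(out) <- NULL
    out
  })
}

# Vectorized decision stage. Returns list(d, first_longer, reference).
decide_trials <- function(observer, x1, x2, trials) {
  UseMethod("decide_trials")
}

#' @export
decide_trials.difference_observer <- function(observer, x1, x2, trials) {
  d <- x1 - x2
  list(d = d, first_longer = d > observer$gamma, reference = rep(NA_real_, length(d)))
}

#' @export
decide_trials.swm_observer <- function(observer, x1, x2, trials) {
  r1 <- if (is.null(observer$r1)) trials$standard else observer$r1
  r2 <- if (is.null(observer$r2)) trials$standard else observer$r2
  d <- (observer$s1 * x1 + (1 - observer$s1) * r1) -
       (observer$s2 * x2 + (1 - observer$s2) * r2)
  list(d = d, first_longer = d > observer$gamma, reference = rep(NA_real_, length(d)))
}

#' @export
decide_trials.irm_observer <- function(observer, x1, x2, trials) {
  g <- observer$g
  n <- length(x1)
  # I[n] = g I[n-1] + (1-g) x1[n] is a linear recursion; run it vectorized.
  init <- switch(observer$i0_policy,
                 first_sensation = x1[1],  # makes I[1] = x1[1]
                 standard_mean = trials$standard[1])
  I <- as.numeric(stats::filter((1 - g) * x1, filter = g,
                                method = "recursive", init = init))
  d <- I - x2
  list(d = d, first_longer = d > observer$gamma, reference = I)
}

#' Simulate an observer through a constant-stimuli trial sequence
#'
#' Draws latent sensations for every trial, applies the observer's decision
#' rule in presentation order (the IRM reference is carried across trials and
#' blocks within the sequence; reset it between regimes by simulating regimes
#' separately), and records the binary judgment. "c longer" always means the
#' comparison was judged longer, regardless of its position.
#'
#' Uses the ambient RNG stream; seed it with `set.seed()` for reproducibility.
#'
#' @param trials Trial data frame from [build_design()].
#' @param observer A `typeb_observer`.
#' @param keep_latents Keep the latent sensations and (for the IRM) the
#'   reference trajectory in the output?
#' @return The trials data frame with columns `response_c_longer` (0/1) and,
#'   if requested, `x1`, `x2`, `reference` appended.
#' @export
run_constant_stimuli <- function(trials, observer, keep_latents = TRUE) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0,
            inherits(observer, "typeb_observer"))
  x1 <- perceive(trials$first_duration, observer$noise)
  x2 <- perceive(trials$second_duration, observer$noise)
  dec <- decide_trials(observer, x1, x2, trials)
  first_longer <- dec$first_longer
  c_longer <- ifelse(trials$order == "sc", !first_longer, first_longer)
  out <- trials
  out$response_c_longer <- as.integer(c_longer)
  if (keep_latents) {
    out$x1 <- x1
    out$x2 <- x2
    out$reference <- dec$reference
  }
  out
}
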