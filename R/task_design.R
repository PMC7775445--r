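#' Task parameters for the Salience Continuous Performance Task
#'
#' The Salience CPT is a 'not-X' continuous performance task: a stream of
#' letters requiring a button press (StandardGo), except for the letter 'X'
#' (NoGo, withhold), extended with a rare physically salient stimulus (a red
#' square, SalientGo) that requires the same response as the letters.  The
#' default parameterization is the published design: 8 blocks of 100 trials,
#' 25% NoGo and 10% SalientGo per block, 150 ms stimulus duration and
#' 1500 ms inter-stimulus interval (1650 ms trial duration).
#'
#' The printed composition admits no ordering with
#' `min_standard_between_specials = 2` StandardGo trials between *every*
#' pair of special (NoGo/SalientGo) stimuli: a 100-trial block holds 35
#' specials, whose 34 gaps would need 68 separators from only 65 standards.
#' The constraint is therefore split: `min_standard_between_specials`
#' applies between specials of the same condition, and `min_standard_cross`
#' (default 1) between a NoGo and a SalientGo.  See the package vignette.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block.
#' @param frac_nogo Proportion of NoGo trials per block.
#' @param frac_salient Proportion of SalientGo trials per block.
#' @param stim_duration Stimulus duration in ms.
#' @param isi Inter-stimulus interval in ms.
#' @param min_standard_between_specials Minimum number of StandardGo trials
#'   between two specials of the same condition.
#' @param min_standard_cross Minimum number of StandardGo trials between a
#'   NoGo and a SalientGo (either order).
#' @param letter_pool Letters used for StandardGo trials; must not contain
#'   "X".
#' @return An object of class `cpt_task_params`.
#' @export
#' @examples
#' p <- cpt_task_params()
#' p$trials_per_block * p$frac_nogo  # 25 NoGo per block
cpt_task_params <- function(n_blocks = 8,
                            trials_per_block = 100,
                            frac_nogo = 0.25,
                            frac_salient = 0.10,
                            stim_duration = 150,
                            isi = 1500,
                            min_standard_between_specials = 2,
                            min_standard_cross = 1,
                            letter_pool = setdiff(LETTERS, "X")) {
  p <- list(n_blocks = as.integer(n_blocks),
            trials_per_block = as.integer(trials_per_block),
            frac_nogo = frac_nogo,
            frac_salient = frac_salient,
            stim_duration = stim_duration,
            isi = isi,
            min_standard_between_specials = as.integer(min_standard_between_specials),
            min_standard_cross = as.integer(min_standard_cross),
            letter_pool = letter_pool)
  class(p) <- "cpt_task_params"
  validate_task_params(p)
  p
}

validate_task_params <- function(p) {
  stopifnot(p$n_blocks >= 1, p$trials_per_block >= 1)
  if (p$frac_nogo + p$frac_salient >= 1)
    stop("frac_nogo + frac_salient must be < 1", call. = FALSE)
  if (p$min_standard_between_specials < 0 || p$min_standard_cross < 0)
    stop("separation minima must be >= 0", call. = FALSE)
  nN <- p$trials_per_block * p$frac_nogo
  nS <- p$trials_per_block * p$frac_salient
  if (abs(nN - round(nN)) > 1e-9 || abs(nS - round(nS)) > 1e-9)
    stop("invalid proportions: per-block NoGo/SalientGo counts are not integers",
         call. = FALSE)
  if ("X" %in% p$letter_pool)
    stop("letter_pool must not contain 'X'", call. = FALSE)
  invisible(p)
}

# Required number of standards between consecutive specials of types a, b.
.sep_req <- function(a, b, g_same, g_cross) ifelse(a == b, g_same, g_cross)

# Minimal number of separator standards achievable for nN NoGo + nS
# SalientGo in one block, over all orderings: every one of the
# (nN + nS - 1) gaps costs g_same except cross-condition adjacencies, of
# which at most 2 * min(nN, nS) can be realised (minority interspersed
# singly; capped by the number of gaps).
.min_separators <- function(nN, nS, g_same, g_cross) {
  n_spec <- nN + nS
  if (n_spec <= 1L) return(0L)
  max_cross <- min(2L * min(nN, nS), n_spec - 1L)
  g_same * (n_spec - 1L) - (g_same - g_cross) * max_cross
}

#' Generate a pseudo-randomized Salience CPT trial sequence
#'
#' Places NoGo and SalientGo trials into each block by sampling a special-
#' condition ordering, computing the minimum StandardGo gap each adjacent
#' pair requires, and distributing the remaining StandardGo trials uniformly
#' at random over the gap slots (constrained shuffle; a deterministic
#' evenly-interleaved ordering is used as repair if ordering rejection
#' stalls, so generation always terminates).  The separation constraint is
#' enforced across block boundaries.
#'
#' @param params A [cpt_task_params()] object.
#' @param seed Integer seed; identical seeds yield identical sequences.
#' @return An object of class `cpt_sequence`: a list with `params` and
#'   `trials`, a data.frame with columns `index` (0-based), `block`
#'   (0-based), `condition` (`StandardGo`/`NoGo`/`SalientGo`), `stimulus`
#'   (letter or `"red_square"`; NoGo is always `"X"`), `onset_ms`.
#' @export
#' @examples
#' seq <- generate_sequence(cpt_task_params(), seed = 1)
#' table(seq$trials$condition)
generate_sequence <- function(params = cpt_task_params(), seed = 1L) {
  validate_task_params(params)
  T_blk <- params$trials_per_block
  nN <- as.integer(round(T_blk * params$frac_nogo))
  nS <- as.integer(round(T_blk * params$frac_salient))
  n_spec <- nN + nS
  n_std <- T_blk - n_spec
  g_same <- params$min_standard_between_specials
  g_cross <- params$min_standard_cross

  if (.min_separators(nN, nS, g_same, g_cross) > n_std)
    stop("unsatisfiable separation constraint: ", n_spec,
         " specials per block cannot be separated by the required number ",
         "of StandardGo trials (", n_std, " available)", call. = FALSE)

  with_seed(seed, {
    B <- params$n_blocks
    if (n_spec == 0L) {
      conditions <- rep("StandardGo", B * T_blk)
    } else {
      # Sample all block orderings jointly; each boundary gap requirement
      # is split between the adjacent blocks (tail of b + lead of b+1), so
      # no block can strand its successor.  Deterministic even-interleave
      # repair guarantees termination.
      plan <- NULL
      for (try in seq_len(200L)) {
        ords <- replicate(B, sample(c(rep("NoGo", nN),
                                      rep("SalientGo", nS))),
                          simplify = FALSE)
        cand <- .block_plan(ords, n_std, g_same, g_cross)
        if (!is.null(cand)) { plan <- cand; break }
      }
      if (is.null(plan)) {
        ords <- replicate(B, .even_interleave(nN, nS), simplify = FALSE)
        plan <- .block_plan(ords, n_std, g_same, g_cross)
        if (is.null(plan))
          stop("unsatisfiable separation constraint across block boundaries",
               call. = FALSE)
      }
      conditions <- character(0)
      for (b in seq_len(B)) {
        ord <- plan$ords[[b]]
        mins <- c(plan$lead[b],
                  if (n_spec > 1L) .sep_req(ord[-n_spec], ord[-1L],
                                            g_same, g_cross) else integer(0),
                  plan$tail[b])
        free <- n_std - sum(mins)
        extra <- as.vector(stats::rmultinom(1L, free,
                                            rep(1, length(mins))))
        counts <- mins + extra
        blk_cond <- character(0)
        for (i in seq_len(n_spec))
          blk_cond <- c(blk_cond, rep("StandardGo", counts[i]), ord[i])
        conditions <- c(conditions,
                        c(blk_cond, rep("StandardGo",
                                        counts[n_spec + 1L])))
      }
    }

    n_tot <- length(conditions)
    stimulus <- character(n_tot)
    is_std <- conditions == "StandardGo"
    stimulus[is_std] <- sample(params$letter_pool, sum(is_std), replace = TRUE)
    stimulus[conditions == "NoGo"] <- "X"
    stimulus[conditions == "SalientGo"] <- "red_square"

    trials <- data.frame(
      index = seq_len(n_tot) - 1L,
      block = rep(seq_len(params$n_blocks) - 1L, each = T_blk),
      condition = conditions,
      stimulus = stimulus,
      onset_ms = (seq_len(n_tot) - 1L) * (params$stim_duration + params$isi),
      stringsAsFactors = FALSE
    )
    structure(list(params = params, trials = trials, seed = as.integer(seed)),
              class = "cpt_sequence")
  })
}

# Given per-block special orderings, allocate the minimum lead/tail
# standards each block owes its boundary gaps; NULL when some block cannot
# host its minima within n_std standards.
.block_plan <- function(ords, n_std, g_same, g_cross) {
  B <- length(ords)
  n_spec <- length(ords[[1L]])
  lead <- integer(B); tail <- integer(B)
  for (b in seq_len(B - 1L)) {
    req <- .sep_req(ords[[b]][n_spec], ords[[b + 1L]][1L], g_same, g_cross)
    tail[b] <- as.integer(ceiling(req / 2))
    lead[b + 1L] <- req - tail[b]
  }
  for (b in seq_len(B)) {
    gaps <- if (n_spec > 1L)
      sum(.sep_req(ords[[b]][-n_spec], ords[[b]][-1L], g_same, g_cross))
    else 0L
    if (lead[b] + gaps + tail[b] > n_std) return(NULL)
  }
  list(ords = ords, lead = lead, tail = tail)
}

# Deterministic repair ordering: minority condition interspersed as evenly
# as possible within the majority, maximising cross-condition adjacencies.
.even_interleave <- function(nN, nS) {
  maj <- if (nN >= nS) "NoGo" else "SalientGo"
  mino <- if (nN >= nS) "SalientGo" else "NoGo"
  n_maj <- max(nN, nS); n_min <- min(nN, nS)
  out <- rep(maj, n_maj)
  if (n_min > 0L) {
    pos <- round(seq(1, n_maj, length.out = n_min))
    res <- character(0)
    j <- 1L
    for (i in seq_len(n_maj)) {
      res <- c(res, out[i])
      if (j <= n_min && i == pos[j]) { res <- c(res, mino); j <- j + 1L }
    }
    out <- res
  }
  out
}

#' @export
print.cpt_sequence <- function(x, ...) {
  tab <- table(x$trials$condition)
  cat("Salience CPT trial sequence\n")
  cat(sprintf("  %d trials in %d blocks (%d per block), trial duration %d ms\n",
              nrow(x$trials), x$params$n_blocks, x$params$trials_per_block,
              x$params$stim_duration + x$params$isi))
  cat("  composition:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Validate a Salience CPT sequence against its design constraints
#'
#' Checks (a) exact per-block composition, (b) same-condition separation,
#' (c) cross-condition separation, and (d) onset arithmetic
#' (`onset = index * (stim_duration + isi)`).  This is a reporting
#' operation: violations are returned, never raised.
#'
#' @param seq A `cpt_sequence` (or a compatible list with `params` and
#'   `trials`).
#' @return A `cpt_constraint_report`: data.frame with columns `check`,
#'   `pass`, `first_violation` (0-based trial index or `NA`), plus an
#'   `all_pass` attribute.
#' @export
validate_sequence <- function(seq) {
  p <- seq$params
  tr <- seq$trials
  nN <- as.integer(round(p$trials_per_block * p$frac_nogo))
  nS <- as.integer(round(p$trials_per_block * p$frac_salient))

  # composition per block
  comp_pass <- TRUE; comp_first <- NA_integer_
  for (blk in unique(tr$block)) {
    sub <- tr[tr$block == blk, ]
    ok <- sum(sub$condition == "NoGo") == nN &&
      sum(sub$condition == "SalientGo") == nS &&
      nrow(sub) == p$trials_per_block
    if (!ok) { comp_pass <- FALSE; comp_first <- sub$index[1]; break }
  }

  # separation, scanned across block boundaries
  spec <- which(tr$condition != "StandardGo")
  same_pass <- TRUE; same_first <- NA_integer_
  cross_pass <- TRUE; cross_first <- NA_integer_
  if (length(spec) > 1L) {
    for (k in seq_len(length(spec) - 1L)) {
      a <- spec[k]; b <- spec[k + 1L]
      n_between <- b - a - 1L            # consecutive specials: all standards
      same <- tr$condition[a] == tr$condition[b]
      req <- if (same) p$min_standard_between_specials else p$min_standard_cross
      if (n_between < req) {
        if (same && same_pass) { same_pass <- FALSE; same_first <- tr$index[b] }
        if (!same && cross_pass) { cross_pass <- FALSE; cross_first <- tr$index[b] }
      }
    }
  }

  onset_ok <- tr$onset_ms == tr$index * (p$stim_duration + p$isi)
  onset_pass <- all(onset_ok)
  onset_first <- if (onset_pass) NA_integer_ else tr$index[which(!onset_ok)[1]]

  # stimulus/condition coupling
  stim_ok <- (tr$condition == "NoGo") == (tr$stimulus == "X") &
    (tr$condition == "SalientGo") == (tr$stimulus == "red_square")
  stim_pass <- all(stim_ok)
  stim_first <- if (stim_pass) NA_integer_ else tr$index[which(!stim_ok)[1]]

  rep <- data.frame(
    check = c("composition", "separation_same", "separation_cross",
              "onset", "stimulus_coupling"),
    pass = c(comp_pass, same_pass, cross_pass, onset_pass, stim_pass),
    first_violation = c(comp_first, same_first, cross_first, onset_first,
                        stim_first),
    stringsAsFactors = FALSE
  )
  attr(rep, "all_pass") <- all(rep$pass)
  class(rep) <- c("cpt_constraint_report", "data.frame")
  rep
}

#' Write a trial sequence as TSV with a JSON sidecar
#'
#' @param seq A `cpt_sequence`.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension and records the generating seed and design
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  utils::write.table(seq$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- sub("\\.tsv$", "", path)
  meta <- list(seed = seq$seed,
               params = seq$params[setdiff(names(seq$params), "letter_pool")],
               letter_pool = paste(seq$params$letter_pool, collapse = ""))
  jsonlite::write_json(meta, paste0(side, ".json"), auto_unbox = TRUE)
  invisible(path)
}
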