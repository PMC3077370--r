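# Calibrated synthetic transcript sets. The generator emulates the study
# conditions the analysis assumes: two labeled groups (5UI- "positive" and
# 5UI+ "negative") of one leader class whose first 69 nt are sampled from a
# leader-like tilted codon model (adenine and thymine weights on a
# hydrophobic-rich amino-acid profile), a planted degenerate motif with
# group-specific presence/multiplicity fractions and 5'-biased positions,
# and group-specific 5'UTR length distributions. Every planted instance is
# recorded in a truth ledger, and the background is scrubbed of spurious
# consensus matches so the ledger is exact.

# Hydrophobic-rich leader-like amino-acid profile (relative weights).
.LEADER_AA_PROFILE <- c(
  L = 0.140, A = 0.110, S = 0.080, V = 0.070, G = 0.070, P = 0.060,
  R = 0.050, C = 0.040, T = 0.050, F = 0.050, W = 0.015, I = 0.045,
  K = 0.030, M = 0.025, Q = 0.030, E = 0.025, D = 0.020, N = 0.020,
  H = 0.020, Y = 0.020)

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

# Codon sampling distribution: profile over amino acids, uniform over
# synonymous codons, tilted by per-codon adenine and thymine weights.
.tilted_codon_probs <- function(profile, w_a = 1, w_t = 1) {
  codons <- .sense_codons()
  aa <- unname(codons)
  syn <- table(aa)
  n_a <- vapply(strsplit(names(codons), ""), function(x) sum(x == "A"), numeric(1))
  n_t <- vapply(strsplit(names(codons), ""), function(x) sum(x == "T"), numeric(1))
  p <- (profile[aa] / as.numeric(syn[aa])) * w_a^n_a * w_t^n_t
  stats::setNames(p / sum(p), names(codons))
}

# Solve the adenine weight so that the expected A count of one leader
# (1 fixed ATG + n_codons tilted codons) equals `target`.
.solve_adenine_tilt <- function(profile, w_t, target, n_codons = 22L) {
  codons <- .sense_codons()
  n_a <- vapply(strsplit(names(codons), ""), function(x) sum(x == "A"), numeric(1))
  mean_a <- function(w_a) {
    p <- .tilted_codon_probs(profile, w_a, w_t)
    1 + n_codons * sum(p * n_a)
  }
  stats::uniroot(function(w) mean_a(w) - target,
                 lower = 1e-04, upper = 50, tol = 1e-10)$root
}

# Exact pmf of an occurrence position over the support 3..hi for the
# planting scheme: single copies draw from the truncated shifted negative
# binomial f; the second copy of a pair is redrawn until it sits at least
# `min_sep` from the first, whose marginal is f conditioned on that
# separation, averaged over the first draw. The occurrence mixture weights
# single-copy and pair positions by their expected counts.
.position_occurrence_pmf <- function(mu, size, hi, min_sep, frac1, frac2) {
  supp <- 3:hi
  f <- stats::dnbinom(supp - 3L, size = size, mu = mu)
  f <- f / sum(f)
  n <- length(supp)
  sep_ok <- abs(outer(supp, supp, "-")) >= min_sep
  s_x <- as.vector(sep_ok %*% f)          # S(x) = P(|y - x| >= min_sep)
  g <- as.vector(t(sep_ok) %*% (f / s_x)) * f  # marginal of the second copy
  w1 <- frac1; w2 <- 2 * frac2
  pmf <- if (w1 + w2 > 0) (w1 * f + w2 * (f + g) / 2) / (w1 + w2) else f
  stats::setNames(pmf, supp)
}

# Solve the negative-binomial mean so that the mid-distribution median of
# the occurrence-position mixture equals `target0` (0-based window start):
# with F(k0) - pmf(k0)/2 = 0.5 the discrete median sits at k0 and the
# sample median fluctuates symmetrically around it.
.solve_position_mu <- function(target0, size, hi, min_sep, frac1, frac2) {
  stats::uniroot(function(mu) {
    pmf <- .position_occurrence_pmf(mu, size, hi, min_sep, frac1, frac2)
    idx <- target0 - 2L     # position of target0 within support 3..hi
    sum(pmf[seq_len(idx)]) - 0.5 * pmf[idx] - 0.5
  }, lower = 0.5, upper = 120, tol = 1e-08)$root
}

#' Configuration of the synthetic dataset
#'
#' Defaults are the study conditions the analysis targets: set sizes 2594
#' (5UI-) and 938 (5UI+); a 0.182 relative adenine depletion in the first 69
#' nt (base median 11 A per 69 nt in the 5UI+ group); leucine:isoleucine and
#' arginine:lysine pooled odds-ratio targets 1.55 and 2.1; planted consensus
#' `CGSSGC` with presence fractions 0.475 / 0.222, multi-copy (>= 2)
#' fractions 0.268 / 0.0714, and 1-based median hit positions 39 / 45;
#' log-normal 5'UTR lengths with medians 126 / 225 nt (99-nt difference).
#'
#' @param n_pos,n_neg Group sizes (5UI- and 5UI+).
#' @param n_other Optional count of unplanted OTHER-class transcripts whose
#'   5UI status depends only on 5'UTR length (for the stratified control).
#' @param cds_length CDS length in nt (multiple of 3, >= 150).
#' @param adenine_depletion Relative median A%% difference between groups.
#' @param adenine_base_median Target median A fraction of the 5UI+ leader.
#' @param leu_ile_or,arg_lys_or Amino-acid profile odds-ratio targets.
#' @param thymine_tilt_pos,thymine_tilt_neg Per-group thymine codon weights.
#' @param motif_consensus Degenerate planted consensus (IUPAC).
#' @param s_weight_pos,s_weight_neg Probability that a degenerate position
#'   instantiates to its first IUPAC option (C for S, A for W), per group.
#'   The 5UI- default is biased (0.6) while the 5UI+ default is unbiased
#'   (0.5), reflecting relaxed selection on non-functional occurrences; this
#'   grades the score levels of planted sites under a site-derived PSSM.
#' @param presence_pos,presence_neg Fractions of sequences with >= 1 planted
#'   copy.
#' @param multi_pos,multi_neg Fractions with >= 2 planted copies
#'   (`multi <= presence`).
#' @param pos_median_pos,pos_median_neg 1-based median planted window start.
#' @param position_shape Negative-binomial size of the position law.
#' @param utr5_median_pos,utr5_median_neg Median 5'UTR lengths (nt).
#' @param utr5_sdlog Log-normal sdlog of the 5'UTR lengths.
#' @param leader_class Leader class assigned to both labeled groups.
#' @param seed Master seed.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos = 2594L, n_neg = 938L, n_other = 0L,
                             cds_length = 300L,
                             adenine_depletion = 0.182,
                             adenine_base_median = 11 / 69,
                             leu_ile_or = 1.55, arg_lys_or = 2.1,
                             thymine_tilt_pos = 0.8, thymine_tilt_neg = 1.0,
                             motif_consensus = "CGSSGC",
                             s_weight_pos = 0.6, s_weight_neg = 0.5,
                             presence_pos = 0.475, presence_neg = 0.222,
                             multi_pos = 0.268, multi_neg = 0.0714,
                             pos_median_pos = 39L, pos_median_neg = 45L,
                             position_shape = 20,
                             utr5_median_pos = 126, utr5_median_neg = 225,
                             utr5_sdlog = 0.6,
                             leader_class = "SSCR", seed = 1L) {
  cfg <- as.list(environment())
  w <- nchar(motif_consensus)
  if (cds_length %% 3 != 0 || cds_length < 150)
    stop("cds_length must be a multiple of 3 and >= 150")
  fr <- c(presence_pos, presence_neg, multi_pos, multi_neg)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (multi_pos > presence_pos || multi_neg > presence_neg)
    stop("multi-copy fraction cannot exceed presence fraction")
  if (pos_median_pos >= 99 - w || pos_median_neg >= 99 - w)
    stop("median position beyond scan region")
  if (adenine_depletion < 0 || adenine_depletion >= 1)
    stop("adenine_depletion must lie in [0, 1)")
  if (any(c(s_weight_pos, s_weight_neg) < 0 | c(s_weight_pos, s_weight_neg) > 1))
    stop("degenerate-position weights must lie in [0, 1]")
  if (!leader_class %in% c("SSCR", "MSCR")) stop("leader_class must be SSCR or MSCR")
  structure(cfg, class = "synthetic_config")
}

.apply_pair_multipliers <- function(base, m_li, m_rk) {
  p <- base
  p["L"] <- p["L"] * sqrt(m_li); p["I"] <- p["I"] / sqrt(m_li)
  p["R"] <- p["R"] * sqrt(m_rk); p["K"] <- p["K"] / sqrt(m_rk)
  p / sum(p)
}

# Expected per-copy amino-acid tally change caused by overwriting the
# background with one planted consensus instance: the motif lands at a
# uniform codon phase; every codon it touches loses its original identity
# (joint distribution of the surviving original bases preserved) and gains
# the identity formed from motif letters plus those survivors. Exact
# enumeration over phases, touched codons, original codons and degenerate
# letter options.
.expected_aa_delta <- function(probs, consensus, s_weight) {
  map <- Biostrings::IUPAC_CODE_MAP
  gc <- Biostrings::GENETIC_CODE
  letters_c <- strsplit(toupper(consensus), "")[[1]]
  w <- length(letters_c)
  letter_dist <- lapply(letters_c, function(l) {
    opts <- strsplit(map[[l]], "")[[1]]
    if (length(opts) == 1L) stats::setNames(1, opts)
    else stats::setNames(c(s_weight,
                           rep((1 - s_weight) / (length(opts) - 1L),
                               length(opts) - 1L)), opts)
  })
  codons <- names(probs)
  cmat <- do.call(rbind, strsplit(codons, ""))
  aa_levels <- sort(unique(gc))
  added <- stats::setNames(numeric(length(aa_levels)), aa_levels)
  removed_codons <- 0
  for (f in 0:2) {
    for (t in 0:((f + w - 1) %/% 3)) {
      slots <- (3 * t):(3 * t + 2)
      is_motif <- slots >= f & slots <= f + w - 1
      midx <- which(is_motif)
      dists <- lapply(midx, function(s) letter_dist[[slots[s] - f + 1L]])
      combos <- expand.grid(lapply(dists, names), stringsAsFactors = FALSE)
      wts <- rep(1, nrow(combos))
      for (j in seq_along(dists))
        wts <- wts * dists[[j]][combos[[j]]]
      if (all(is_motif)) {
        for (r in seq_len(nrow(combos))) {
          cd <- paste0(combos[r, 1], combos[r, 2], combos[r, 3])
          added[gc[cd]] <- added[gc[cd]] + wts[r] / 3
        }
      } else {
        for (ci in seq_along(codons)) {
          pc <- probs[ci]
          if (pc == 0) next
          for (r in seq_len(nrow(combos))) {
            bases <- cmat[ci, ]
            bases[midx] <- unlist(combos[r, ], use.names = FALSE)
            cd <- paste0(bases[1], bases[2], bases[3])
            added[gc[cd]] <- added[gc[cd]] + pc * wts[r] / 3
          }
        }
      }
      removed_codons <- removed_codons + 1 / 3
    }
  }
  list(added = added, removed_codons = removed_codons)
}

# Expected pooled count of one amino acid over the 22 sampled leader codons
# of a sequence, adjusted for the expected planted copies.
.expected_aa_count <- function(probs, a, delta, exp_copies) {
  aa <- unname(.sense_codons())
  base <- 22 * sum(probs[aa == a])
  base + exp_copies *
    (delta$added[[a]] - delta$removed_codons * sum(probs[aa == a]))
}

# Expected count ratio of two amino acids, planting-adjusted.
.aa_pair_ratio <- function(probs, a1, a2, delta = NULL, exp_copies = 0) {
  if (is.null(delta)) {
    aa <- unname(.sense_codons())
    return(sum(probs[aa == a1]) / sum(probs[aa == a2]))
  }
  .expected_aa_count(probs, a1, delta, exp_copies) /
    .expected_aa_count(probs, a2, delta, exp_copies)
}

# Calibrate the positive-group profile multipliers so that the post-tilt
# pooled L:I and R:K odds ratios (relative to the realized negative-group
# ratios) hit their configured targets; the adenine weight is re-solved at
# each step because the tilt and the profile interact.
.calibrate_pos_profile <- function(base, or_li, or_rk, w_t, target_a,
                                   r_li_neg, r_rk_neg, consensus, s_weight,
                                   exp_copies) {
  m_li <- or_li; m_rk <- or_rk
  for (iter in 1:8) {
    prof <- .apply_pair_multipliers(base, m_li, m_rk)
    w_a <- .solve_adenine_tilt(prof, w_t, target_a)
    probs <- .tilted_codon_probs(prof, w_a, w_t)
    delta <- .expected_aa_delta(probs, consensus, s_weight)
    cur_li <- .aa_pair_ratio(probs, "L", "I", delta, exp_copies) / r_li_neg
    cur_rk <- .aa_pair_ratio(probs, "R", "K", delta, exp_copies) / r_rk_neg
    if (max(abs(log(c(cur_li / or_li, cur_rk / or_rk)))) < 1e-06) break
    m_li <- m_li * (or_li / cur_li)
    m_rk <- m_rk * (or_rk / cur_rk)
  }
  list(profile = prof, w_a = w_a, probs = probs,
       m_li = m_li, m_rk = m_rk)
}

# Instantiate a degenerate consensus n times: degenerate positions draw
# their first IUPAC option with probability `weight`, uniform over the rest
# of the option set otherwise.
.instantiate_consensus <- function(consensus, n, weight = 0.5) {
  map <- Biostrings::IUPAC_CODE_MAP
  letters_c <- strsplit(toupper(consensus), "")[[1]]
  cols <- lapply(letters_c, function(l) {
    opts <- strsplit(map[[l]], "")[[1]]
    if (length(opts) == 1L) rep(opts, n) else {
      first <- stats::runif(n) < weight
      out <- character(n)
      out[first] <- opts[1]
      if (any(!first)) out[!first] <- sample(opts[-1], sum(!first),
                                             replace = TRUE)
      out
    }
  })
  do.call(paste0, cols)
}

# 0-based consensus match positions of `consensus` within the first
# `region` nt of each sequence; returns a list of integer vectors.
.find_consensus_matches <- function(seqs, consensus, region = 99L) {
  insts <- .expand_consensus(consensus)
  w <- nchar(consensus)
  lapply(seqs, function(s) {
    sub <- substr(s, 1, min(region, nchar(s)))
    L <- nchar(sub)
    if (L < w) return(integer(0))
    wins <- substring(sub, 1:(L - w + 1), w:L)
    which(wins %in% insts) - 1L
  })
}

# Replace one base of each spurious (non-planted) consensus match with A or
# T, choosing an offset outside every planted window. For consensus
# alphabets without A/W and T/W letters this cannot create new matches.
.scrub_spurious <- function(seq, planted, consensus, region = 99L) {
  w <- nchar(consensus)
  for (iter in 1:25) {
    m <- .find_consensus_matches(seq, consensus, region)[[1]]
    spurious <- setdiff(m, planted)
    if (!length(spurious)) return(seq)
    q <- spurious[1]
    in_planted <- function(pos) any(pos >= planted & pos < planted + w)
    off <- which(!vapply(q + 0:(w - 1L), in_planted, logical(1)))[1]
    if (is.na(off)) return(seq)  # fully covered by planted copies; leave it
    pos1 <- q + off  # 0-based -> substr is 1-based
    substr(seq, pos1, pos1) <- sample(c("A", "T"), 1)
  }
  seq
}

#' Generate a labeled synthetic transcript set
#'
#' See [synthetic_config()] for the generative model. The adenine tilt of
#' each group is solved so that the post-planting median A count of the
#' first 69 nt lands on the configured target (the planted motif is A-free,
#' so its expected overwrite is corrected for); planted positions follow a
#' shifted negative binomial whose discrete median equals the configured
#' value; 5'UTR lengths are log-normal. The 5UI+ group carries one 5'UTR
#' intron.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_dataset` with `records` (transcript
#'   records), `truth` (data.frame of planted instances: `transcript_id`,
#'   `position` 0-based, `instance`), and `params` (solved tilts and
#'   realized group statistics).
#' @export
gen_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  w <- nchar(cfg$motif_consensus)
  codons <- names(.sense_codons())
  prof_neg <- .LEADER_AA_PROFILE / sum(.LEADER_AA_PROFILE)
  target_neg <- cfg$adenine_base_median * 69
  target_pos <- (1 - cfg$adenine_depletion) * target_neg
  # correct for expected planted overwrite (planted copies carry no A)
  exp_copies <- function(presence, multi) (presence - multi) + 2 * multi
  scale_pos <- 1 - w * exp_copies(cfg$presence_pos, cfg$multi_pos) / 69
  scale_neg <- 1 - w * exp_copies(cfg$presence_neg, cfg$multi_neg) / 69
  w_a_neg <- .solve_adenine_tilt(prof_neg, cfg$thymine_tilt_neg,
                                 target_neg / scale_neg)
  probs_neg <- .tilted_codon_probs(prof_neg, w_a_neg, cfg$thymine_tilt_neg)
  ec_pos <- exp_copies(cfg$presence_pos, cfg$multi_pos)
  ec_neg <- exp_copies(cfg$presence_neg, cfg$multi_neg)
  delta_neg <- .expected_aa_delta(probs_neg, cfg$motif_consensus,
                                  cfg$s_weight_neg)
  cal <- .calibrate_pos_profile(
    prof_neg, cfg$leu_ile_or, cfg$arg_lys_or, cfg$thymine_tilt_pos,
    target_pos / scale_pos,
    .aa_pair_ratio(probs_neg, "L", "I", delta_neg, ec_neg),
    .aa_pair_ratio(probs_neg, "R", "K", delta_neg, ec_neg),
    cfg$motif_consensus, cfg$s_weight_pos, ec_pos)
  w_a_pos <- cal$w_a
  probs_pos <- cal$probs
  probs_bg <- .tilted_codon_probs(prof_neg, 1, 1)
  hi_pos <- 99L - w
  mu_pos <- .solve_position_mu(cfg$pos_median_pos - 1L, cfg$position_shape,
                               hi_pos, 2L * w - 1L,
                               cfg$presence_pos - cfg$multi_pos,
                               cfg$multi_pos)
  mu_neg <- .solve_position_mu(cfg$pos_median_neg - 1L, cfg$position_shape,
                               hi_pos, 2L * w - 1L,
                               cfg$presence_neg - cfg$multi_neg,
                               cfg$multi_neg)
  n_rest <- (cfg$cds_length - 69L) / 3L - 1L  # background codons before the stop

  gen_group <- function(n, probs_leader, presence, multi, mu, utr5_median,
                        has_5ui, id_offset, s_weight) {
    if (n == 0L) return(NULL)
    draw_codons <- function(k, p) matrix(
      sample(codons, n * k, replace = TRUE, prob = p), nrow = n)
    leader <- cbind("ATG", draw_codons(22L, probs_leader))
    rest <- cbind(draw_codons(n_rest, probs_bg), "TAA")
    seqs <- paste0(apply(leader, 1, paste, collapse = ""),
                   apply(rest, 1, paste, collapse = ""))
    # exact planted composition (up to rounding), randomly assigned: the
    # configured fractions are the study conditions, not sampling targets
    n2 <- round(n * multi)
    n1 <- round(n * presence) - n2
    copies <- sample(c(rep(2L, n2), rep(1L, n1), rep(0L, n - n1 - n2)))
    draw_pos <- function() {
      repeat {
        p <- 3L + stats::rnbinom(1L, size = cfg$position_shape, mu = mu)
        if (p <= 99L - w) return(p)
      }
    }
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      k <- copies[i]
      if (k == 0L) next
      pos <- draw_pos()
      if (k == 2L) {
        # separation >= 2w-1 so no window can straddle both copies without
        # containing a (scrubbable) background base
        repeat {
          p2 <- draw_pos()
          if (abs(p2 - pos) >= 2L * w - 1L) break
        }
        pos <- sort(c(pos, p2))
      }
      inst <- .instantiate_consensus(cfg$motif_consensus, k, s_weight)
      s <- seqs[i]
      for (j in seq_len(k)) {
        substr(s, pos[j] + 1L, pos[j] + w) <- inst[j]
      }
      seqs[i] <- s
      truth[[i]] <- data.frame(idx = i, position = pos, instance = inst,
                               stringsAsFactors = FALSE)
    }
    planted_by_seq <- lapply(truth, function(t) if (is.null(t)) integer(0) else t$position)
    for (i in seq_len(n))
      seqs[i] <- .scrub_spurious(seqs[i], planted_by_seq[[i]],
                                 cfg$motif_consensus)
    # quantile-matched log-normal draw: a random permutation of the
    # distribution's empirical quantiles, so the realized median equals the
    # configured one up to rounding (the length condition is a condition,
    # not a sampling target)
    utr5 <- round(stats::qlnorm(sample((seq_len(n) - 0.5) / n),
                                meanlog = log(utr5_median),
                                sdlog = cfg$utr5_sdlog))
    utr5 <- pmax(utr5, if (has_5ui) 10 else 0)
    ids <- sprintf("SIM%05d", id_offset + seq_len(n))
    rec <- data.frame(transcript_id = ids, cds = seqs,
                      utr5_length = as.integer(utr5),
                      utr5_intron_count = if (has_5ui) 1L else 0L,
                      has_5ui = has_5ui, leader_class = cfg$leader_class,
                      stringsAsFactors = FALSE)
    tr <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (!is.null(tr)) {
      tr$transcript_id <- ids[tr$idx]
      tr <- tr[, c("transcript_id", "position", "instance")]
    }
    list(records = rec, truth = tr)
  }

  out <- withr::with_seed(cfg$seed, {
    pos <- gen_group(cfg$n_pos, probs_pos, cfg$presence_pos, cfg$multi_pos,
                     mu_pos, cfg$utr5_median_pos, FALSE, 0L,
                     cfg$s_weight_pos)
    neg <- gen_group(cfg$n_neg, probs_neg, cfg$presence_neg, cfg$multi_neg,
                     mu_neg, cfg$utr5_median_neg, TRUE, cfg$n_pos,
                     cfg$s_weight_neg)
    other <- NULL
    if (cfg$n_other > 0L) {
      n <- cfg$n_other
      draw <- matrix(sample(codons, n * (22L + n_rest), replace = TRUE,
                            prob = probs_bg), nrow = n)
      seqs <- paste0("ATG", apply(draw, 1, paste, collapse = ""), "TAA")
      mix <- stats::runif(n) < 0.35
      utr5 <- round(stats::rlnorm(n, meanlog = log(ifelse(
        mix, cfg$utr5_median_neg, cfg$utr5_median_pos)),
        sdlog = cfg$utr5_sdlog))
      lu <- log(pmax(utr5, 1))
      off <- stats::uniroot(function(a)
        mean(stats::plogis(a + 1.5 * (lu - mean(lu)))) - 0.35,
        lower = -20, upper = 20)$root
      has_ui <- stats::runif(n) < stats::plogis(off + 1.5 * (lu - mean(lu)))
      utr5 <- pmax(utr5, ifelse(has_ui, 10, 0))
      other <- data.frame(
        transcript_id = sprintf("SIM%05d",
                                cfg$n_pos + cfg$n_neg + seq_len(n)),
        cds = seqs, utr5_length = as.integer(utr5),
        utr5_intron_count = as.integer(has_ui), has_5ui = has_ui,
        leader_class = "OTHER", stringsAsFactors = FALSE)
    }
    list(pos = pos, neg = neg, other = other)
  })
  records <- rbind(out$pos$records, out$neg$records, out$other)
  truth <- rbind(out$pos$truth, out$neg$truth)
  realized <- function(grp_rec, grp_truth) {
    n <- nrow(grp_rec)
    if (is.null(grp_truth))
      return(list(presence = 0, multi = 0,
                  median_position_1based = NA_real_))
    cnt <- table(factor(grp_truth$transcript_id,
                        levels = grp_rec$transcript_id))
    list(presence = sum(cnt >= 1) / n, multi = sum(cnt >= 2) / n,
         median_position_1based = stats::median(grp_truth$position) + 1)
  }
  params <- list(
    w_a_pos = w_a_pos, w_a_neg = w_a_neg, mu_pos = mu_pos, mu_neg = mu_neg,
    realized_pos = if (!is.null(out$pos))
      realized(out$pos$records, out$pos$truth) else NULL,
    realized_neg = if (!is.null(out$neg))
      realized(out$neg$records, out$neg$truth) else NULL)
  structure(list(records = records, truth = truth, params = params,
                 config = cfg),
            class = "synthetic_dataset")
}

#' Realize transcript records as a refGene-like annotation table
#'
#' Lays the transcripts on a simulated chromosome so that re-deriving the
#' 5'UTR attributes from the table reproduces each record's `utr5_length`
#' and 5UI status exactly. Transcripts with a 5'UTR intron get one intron of
#' `intron_length` nt splitting the 5'UTR in half.
#'
#' @param records Transcript-record data.frame.
#' @param strand `"+"` or `"-"` (minus-strand rows are coordinate-mirrored).
#' @param chrom Chromosome name.
#' @param intron_length 5'UTR intron length in nt.
#' @param gap Intergenic gap in nt.
#' @return Data.frame in refGene column layout (see
#'   [read_annotation_table()]).
#' @export
gen_annotation_table <- function(records, strand = "+", chrom = "chrSim",
                                 intron_length = 500L, gap = 1000L) {
  n <- nrow(records)
  rows <- vector("list", n)
  offset <- 0L
  for (i in seq_len(n)) {
    u <- records$utr5_length[i]
    clen <- nchar(records$cds[i])
    has_ui <- records$utr5_intron_count[i] > 0L
    if (has_ui && u < 2) stop("5UI transcript needs a 5'UTR of >= 2 nt")
    if (has_ui) {
      u1 <- u %/% 2L; u2 <- u - u1
      starts <- c(offset, offset + u1 + intron_length)
      ends <- c(offset + u1, offset + u1 + intron_length + u2 + clen)
      cds_start <- offset + u1 + intron_length + u2
    } else {
      starts <- offset
      ends <- offset + u + clen
      cds_start <- offset + u
    }
    cds_end <- ends[length(ends)]
    tx_start <- starts[1]; tx_end <- ends[length(ends)]
    if (strand == "-") {
      C <- tx_start + tx_end  # mirror within the transcript's own span
      new_starts <- sort(C - ends)
      new_ends <- sort(C - starts)
      nc_start <- C - cds_end; nc_end <- C - cds_start
      starts <- new_starts; ends <- new_ends
      cds_start <- nc_start; cds_end <- nc_end
    }
    rows[[i]] <- data.frame(
      name = records$transcript_id[i], chrom = chrom, strand = strand,
      txStart = starts[1], txEnd = ends[length(ends)],
      cdsStart = cds_start, cdsEnd = cds_end, exonCount = length(starts),
      exonStarts = paste0(paste(starts, collapse = ","), ","),
      exonEnds = paste0(paste(ends, collapse = ","), ","),
      stringsAsFactors = FALSE)
    offset <- ends[length(ends)] + gap
  }
  do.call(rbind, rows)
}

#' Write an annotation table as TSV
#'
#' @param ann_df Output of [gen_annotation_table()].
#' @param path Output file.
#' @export
write_annotation_table <- function(ann_df, path) {
  utils::write.table(ann_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate flat category annotations with optional planted terms
#'
#' Unplanted terms are uniform random subsets; planted terms draw members by
#' weighted sampling without replacement with weight `or` on 5UI+
#' transcripts (a biased-urn approximation of the target odds ratio; `or =
#' 0` excludes 5UI+ members entirely). Realized odds ratios are recorded in
#' the `"planted"` attribute.
#'
#' @param records Transcript-record data.frame.
#' @param n_terms Number of unplanted random terms.
#' @param planted List of `list(size =, or =)` specifications.
#' @param size_range Size range of unplanted terms.
#' @param seed Integer seed.
#' @return Named list of term member-id vectors.
#' @export
gen_category_annotations <- function(records, n_terms, planted = list(),
                                     size_range = c(10L, 50L), seed = 1L) {
  ids <- records$transcript_id
  lab <- records$has_5ui
  N <- length(ids); m <- sum(lab)
  for (p in planted) {
    if (p$size < 1 || p$size > N) stop("infeasible planted term size")
    if (p$or == 0 && p$size > N - m)
      stop("infeasible OR for term size: not enough 5UI- transcripts")
  }
  out <- withr::with_seed(seed, {
    terms <- list()
    for (j in seq_along(planted)) {
      p <- planted[[j]]
      wgt <- ifelse(lab, p$or, 1)
      terms[[sprintf("PLANT%02d", j)]] <-
        sample(ids, p$size, prob = wgt)
    }
    for (j in seq_len(n_terms)) {
      s <- sample(seq(size_range[1], size_range[2]), 1L)
      terms[[sprintf("T%04d", j)]] <- sample(ids, s)
    }
    terms
  })
  realized <- lapply(utils::head(names(out), length(planted)), function(t) {
    k <- sum(lab[match(out[[t]], ids)])
    s <- length(out[[t]])
    list(term = t, k_5ui = k,
         or = (k * ((N - m) - (s - k))) / ((s - k) * (m - k)))
  })
  attr(out, "planted") <- realized
  out
}

#' Write a synthetic dataset to a directory
#'
#' Emits the FASTA coding sequences, the refGene-like annotation TSV, the
#' leader-class id lists, the planted-truth TSV (positions 1-based in the
#' file) and a JSON echo of the configuration.
#'
#' @param dataset A [gen_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param strand Strand for the annotation realization.
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir, strand = "+") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "cds.fasta"),
             annotation = file.path(dir, "annotation.tsv"),
             sscr = file.path(dir, "ids_sscr.txt"),
             mscr = file.path(dir, "ids_mscr.txt"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  rec <- dataset$records
  write_cds_fasta(rec, paths["fasta"])
  write_annotation_table(gen_annotation_table(rec, strand = strand),
                         paths["annotation"])
  for (cls in c("SSCR", "MSCR")) {
    ids <- rec$transcript_id[rec$leader_class == cls]
    writeLines(c(paste0("# ", cls, " transcript ids"), ids),
               paths[tolower(cls)])
  }
  tr <- dataset$truth
  if (is.null(tr)) tr <- data.frame(transcript_id = character(0),
                                    position = integer(0),
                                    instance = character(0))
  tr_out <- data.frame(transcript_id = tr$transcript_id,
                       position_1based = tr$position + 1L,
                       instance = tr$instance, stringsAsFactors = FALSE)
  utils::write.table(tr_out, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
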