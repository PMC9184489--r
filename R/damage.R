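# Terminal deamination profiling and the exponential damage model
# f(i) = e + d0 * exp(-lambda * i), the package's parameterisation of the
# C-to-T / G-to-A substitution excess that authenticates ancient DNA.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Profile terminal C-to-T and G-to-A substitution frequencies
#'
#' For every alignment, aligned bases are put in molecule orientation (the
#' strand the fragment was sequenced on): `f_CT[i]` is the fraction of
#' reference-`C` positions at 0-based distance `i` from the molecule's 5'
#' end that read `T`; `f_GA` is the symmetric quantity from the 3' end.
#' Per-alignment contributions are retained so the profile can be
#' bootstrapped by read resampling.
#'
#' @param alignments alignment data frame from [map_reads()].
#' @param anchor anchor genome sequence the alignments refer to.
#' @param w window width in bp from each terminus (default 25).
#' @return object of class `damage_profile`: list with `w`, `f_ct`, `f_ga`
#'   (length-`w` frequency vectors, `NA` where the denominator is zero),
#'   `den_ct`, `den_ga`, `num_ct`, `num_ga`, `n_alignments`, and per-read
#'   contribution matrices `contrib` for bootstrapping.
#' @export
profile_damage <- function(alignments, anchor, w = 25L) {
  if (w < 5) stop("input error: window w must be >= 5")
  n <- nrow(alignments)
  if (n == 0) stop("input error: empty alignment set")
  lens <- nchar(alignments$seq_aln)
  pure_m <- grepl("^[0-9]+M$", alignments$cigar)
  # molecule-oriented read and reference strings per alignment
  qmol <- character(n)
  rmol <- character(n)
  ref_sub <- substring(anchor, alignments$start, alignments$end)
  anchor_chars <- if (all(pure_m)) NULL else strsplit(anchor, "")[[1]]
  for (i in seq_len(n)) {
    if (pure_m[i]) {
      qs <- alignments$seq_aln[i]
      rs <- ref_sub[i]
    } else {
      pr <- aligned_pairs(alignments$start[i], alignments$cigar[i], lens[i])
      ch_q <- strsplit(alignments$seq_aln[i], "")[[1]][pr$qpos]
      ch_r <- anchor_chars[pr$rpos]
      qs <- paste(ch_q, collapse = "")
      rs <- paste(ch_r, collapse = "")
    }
    if (alignments$strand[i] == "-") {
      qs <- revcomp(qs)
      rs <- revcomp(rs)
    }
    qmol[i] <- qs
    rmol[i] <- rs
  }
  alens <- nchar(qmol)
  bq <- strsplit(paste(qmol, collapse = ""), "")[[1]]
  br <- strsplit(paste(rmol, collapse = ""), "")[[1]]
  fid <- rep(seq_len(n), alens)
  d5 <- sequence(alens) - 1L
  d3 <- rep(alens, alens) - sequence(alens)
  acc <- function(mask, d) {
    idx <- (fid[mask] - 1L) * w + d[mask] + 1L
    matrix(tabulate(idx, nbins = n * w), nrow = n, byrow = TRUE)
  }
  den_ct_m <- acc(br == "C" & d5 < w, d5)
  num_ct_m <- acc(br == "C" & bq == "T" & d5 < w, d5)
  den_ga_m <- acc(br == "G" & d3 < w, d3)
  num_ga_m <- acc(br == "G" & bq == "A" & d3 < w, d3)
  den_ct <- colSums(den_ct_m); num_ct <- colSums(num_ct_m)
  den_ga <- colSums(den_ga_m); num_ga <- colSums(num_ga_m)
  structure(list(
    w = as.integer(w),
    f_ct = ifelse(den_ct > 0, num_ct / den_ct, NA),
    f_ga = ifelse(den_ga > 0, num_ga / den_ga, NA),
    num_ct = num_ct, den_ct = den_ct, num_ga = num_ga, den_ga = den_ga,
    n_alignments = n,
    contrib = list(num_ct = num_ct_m, den_ct = den_ct_m,
                   num_ga = num_ga_m, den_ga = den_ga_m)
  ), class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("<damage_profile> ", x$n_alignments, " alignments, w=", x$w,
      "; f_CT[0]=", signif(x$f_ct[1], 3), ", f_GA[0]=", signif(x$f_ga[1], 3),
      "\n", sep = "")
  invisible(x)
}

#' Fit the exponential damage model to a profile
#'
#' Weighted nonlinear least squares of `f(i) = e + d0 * exp(-lambda * i)` on
#' the pooled 5' C-to-T and 3' G-to-A curves, weights equal to the
#' position-wise denominators; bounds `d0, e` in `[0, 1]`, `lambda` in
#' `[0, 5]`. A degenerate (flat) profile returns `d0 = 0` with a flag rather
#' than an error.
#'
#' @param profile a `damage_profile`.
#' @return object of class `damage_params`: list with `d0`, `lambda`, `e`,
#'   `residual` (weighted RMSE) and `flag` (`"ok"`, `"degenerate"`, or
#'   `"no_signal"` when the optimiser finds no decaying component).
#' @export
fit_damage <- function(profile) {
  stopifnot(inherits(profile, "damage_profile"))
  i <- c(seq_len(profile$w), seq_len(profile$w)) - 1L
  f <- c(profile$f_ct, profile$f_ga)
  den <- c(profile$den_ct, profile$den_ga)
  ok <- den > 0 & !is.na(f)
  if (sum(ok) < 5)
    stop("input error: fewer than 5 defined profile positions")
  i <- i[ok]; f <- f[ok]; den <- den[ok]
  wrmse <- function(pred) sqrt(sum(den * (f - pred)^2) / sum(den))
  if (diff(range(f)) < 1e-12) {
    return(structure(list(d0 = 0, lambda = 0, e = mean(f),
                          residual = wrmse(mean(f)), flag = "degenerate"),
                     class = "damage_params"))
  }
  e0 <- min(f)
  d00 <- max(f[i == min(i)][1] - e0, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ e + d0 * exp(-lambda * i),
      start = list(e = e0, d0 = d00, lambda = 0.3),
      lower = c(0, 0, 0), upper = c(1, 1, 5),
      weights = den,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200)
    ),
    error = function(err) NULL
  )
  if (is.null(fit)) {
    e_hat <- sum(den * f) / sum(den)
    return(structure(list(d0 = 0, lambda = 0, e = e_hat,
                          residual = wrmse(e_hat), flag = "no_signal"),
                     class = "damage_params"))
  }
  cf <- stats::coef(fit)
  # identifiability guard: at lambda -> 0 the decaying term is exchangeable
  # with the background e, and a flat profile can come back as d0 = e,
  # lambda = 0. Keep a nonzero amplitude only if the exponential model beats
  # the constant model (nested weighted-RSS F ratio, 2 extra parameters).
  e_hat <- sum(den * f) / sum(den)
  rss0 <- sum(den * (f - e_hat)^2)
  rss1 <- sum(den * (f - stats::predict(fit))^2)
  q <- length(f)
  f_ratio <- if (rss1 <= rss0 * 1e-12) Inf else
    ((rss0 - rss1) / 2) / (rss1 / max(q - 3, 1))
  if (is.nan(f_ratio) || f_ratio < 4) {
    return(structure(list(d0 = 0, lambda = 0, e = e_hat,
                          residual = wrmse(e_hat), flag = "no_signal"),
                     class = "damage_params"))
  }
  structure(list(d0 = unname(cf["d0"]), lambda = unname(cf["lambda"]),
                 e = unname(cf["e"]),
                 residual = wrmse(stats::predict(fit)), flag = "ok"),
            class = "damage_params")
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf("<damage_params> d0=%.4f lambda=%.4f e=%.5f (rmse %.2e, %s)\n",
              x$d0, x$lambda, x$e, x$residual, x$flag))
  invisible(x)
}

#' Authenticate a sample as ancient from its damage profile
#'
#' Descriptive authentication report: bootstrap interval of the terminal
#' amplitude `d0` (resampling alignments), a monotone-decay check (sign of
#' the Spearman correlation of `f_CT` with distance), and a verdict string.
#' With at least `min_obs` alignments, `d0 >= d0_min` and a negative decay
#' the sample is `"consistent with ancient"`; otherwise `"no damage signal"`;
#' below `min_obs` alignments, `"insufficient data"`.
#'
#' @param params `damage_params` from [fit_damage()].
#' @param profile the `damage_profile` the parameters were fitted on.
#' @param n_boot bootstrap replicates (default 200).
#' @param d0_min amplitude threshold for the ancient verdict (default 0.05;
#'   a surfaced package default, not a community constant).
#' @param min_obs minimum number of alignments for any verdict.
#' @param seed seed of the bootstrap resampling.
#' @return list with `verdict`, `d0`, `d0_ci` (2.5/97.5% bootstrap
#'   quantiles), `decay_rho` (Spearman), `n_alignments`, `n_boot`.
#' @export
authenticate_damage <- function(params, profile, n_boot = 200L,
                                d0_min = 0.05, min_obs = 100L, seed = 1L) {
  stopifnot(inherits(params, "damage_params"),
            inherits(profile, "damage_profile"))
  n <- profile$n_alignments
  ok <- !is.na(profile$f_ct)
  rho <- if (sum(ok) >= 3) {
    suppressWarnings(cor(profile$f_ct[ok], which(ok), method = "spearman"))
  } else NA
  d0_ci <- c(NA_real_, NA_real_)
  if (n >= min_obs && n_boot > 0) {
    boots <- with_seed(child_seed(seed, "damage_boot"), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        bp <- profile
        bp$num_ct <- colSums(profile$contrib$num_ct[idx, , drop = FALSE])
        bp$den_ct <- colSums(profile$contrib$den_ct[idx, , drop = FALSE])
        bp$num_ga <- colSums(profile$contrib$num_ga[idx, , drop = FALSE])
        bp$den_ga <- colSums(profile$contrib$den_ga[idx, , drop = FALSE])
        bp$f_ct <- ifelse(bp$den_ct > 0, bp$num_ct / bp$den_ct, NA)
        bp$f_ga <- ifelse(bp$den_ga > 0, bp$num_ga / bp$den_ga, NA)
        tryCatch(fit_damage(bp)$d0, error = function(e) NA_real_)
      }, numeric(1))
    })
    d0_ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  verdict <- if (n < min_obs) {
    "insufficient data"
  } else if (!is.na(rho) && rho < 0 && params$d0 >= d0_min) {
    "consistent with ancient"
  } else {
    "no damage signal"
  }
  list(verdict = verdict, d0 = params$d0, d0_ci = d0_ci, decay_rho = rho,
       n_alignments = n, n_boot = if (n >= min_obs) n_boot else 0L)
}

#' Write a damage profile as TSV
#'
#' Columns: `end` (`5p`/`3p`), `pos_0based`, `numerator`, `denominator`,
#' `freq`.
#'
#' @param profile a `damage_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_damage_profile <- function(profile, path) {
  df <- data.frame(
    end = rep(c("5p", "3p"), each = profile$w),
    pos_0based = c(seq_len(profile$w), seq_len(profile$w)) - 1L,
    numerator = c(profile$num_ct, profile$num_ga),
    denominator = c(profile$den_ct, profile$den_ga),
    freq = ifelse(c(profile$den_ct, profile$den_ga) > 0,
                  sprintf("%.6f", c(profile$f_ct, profile$f_ga)), "NA"),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Write damage parameters as JSON
#'
#' @param params a `damage_params`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_damage_params <- function(params, path) {
  jsonlite::write_json(params[c("d0", "lambda", "e", "residual", "flag")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
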