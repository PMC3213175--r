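BASES <- c("A", "C", "G", "T")

# HKY85 rate matrix (rows/cols A,C,G,T): transitions (A<->G, C<->T) at rate
# kappa * pi_j, transversions at pi_j, scaled so the expected number of
# substitutions per site per unit branch length is 1.
hky_rate_matrix <- function(kappa, freqs) {
  stopifnot(length(freqs) == 4L, all(freqs > 0), kappa > 0)
  freqs <- freqs / sum(freqs)
  is_transition <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  Q <- matrix(rep(freqs, each = 4), 4, 4, dimnames = list(BASES, BASES))
  Q[is_transition] <- Q[is_transition] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Transition probability matrix P(t) = exp(Qt) computed through the
# symmetric form D^{1/2} Q D^{-1/2} (valid for any reversible model).
hky_transition_probs <- function(t, kappa, freqs) {
  freqs <- freqs / sum(freqs)
  Q <- hky_rate_matrix(kappa, freqs)
  d <- sqrt(freqs)
  S <- (d %o% (1 / d)) * Q
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- (1 / d) * (e$vectors %*% (exp(e$values * t) * t(e$vectors))) * rep(d, each = 4)
  P[P < 0] <- 0
  dimnames(P) <- list(BASES, BASES)
  P
}

# Compress a gap/N-free trio alignment into site-pattern counts over the
# 64 ordered (human, chimp, orang) base triples.
trio_site_patterns <- function(rows) {
  stopifnot(all(c("human", "chimp", "orang") %in% names(rows)))
  mat <- vapply(rows[c("human", "chimp", "orang")],
                function(r) match(alignment_chars(toupper(r)), BASES),
                integer(nchar(rows[[1]])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  idx <- (mat[, 1] - 1L) * 16L + (mat[, 2] - 1L) * 4L + mat[, 3]
  counts <- tabulate(idx, nbins = 64L)
  present <- which(counts > 0L)
  list(
    human = ((present - 1L) %/% 16L) + 1L,
    chimp = ((present - 1L) %/% 4L) %% 4L + 1L,
    orang = (present - 1L) %% 4L + 1L,
    counts = counts[present],
    n_sites = nrow(mat),
    base_counts = tabulate(mat, nbins = 4L)
  )
}

hky_trio_loglik <- function(t_human, t_chimp, t_orang, kappa, freqs, pat) {
  Ph <- hky_transition_probs(t_human, kappa, freqs)
  Pc <- hky_transition_probs(t_chimp, kappa, freqs)
  Po <- hky_transition_probs(t_orang, kappa, freqs)
  site_lik <- colSums(freqs * Ph[, pat$human, drop = FALSE] *
                        Pc[, pat$chimp, drop = FALSE] *
                        Po[, pat$orang, drop = FALSE])
  sum(pat$counts * log(pmax(site_lik, 1e-300)))
}

#' Fit HKY85 branch lengths on the three-taxon tree
#'
#' Maximum-likelihood estimation of the three terminal branch lengths
#' (human, chimpanzee, orangutan) and the transition/transversion ratio
#' kappa on the unrooted star topology, under the HKY85 substitution model
#' with empirical base frequencies. The human and chimpanzee branch lengths
#' are the lineage-specific substitution rates of interest; the orangutan
#' branch absorbs the outgroup path. Columns containing a gap or `N` in any
#' row are excluded before fitting.
#'
#' @param alignment A [trio_alignment()], or a named character vector / list
#'   with elements `human`, `chimp`, `orang` holding equal-length aligned
#'   sequences.
#' @param gene_id Optional identifier carried into the result (taken from a
#'   `trio_alignment` automatically).
#' @param init Optional starting values, a named list with any of `t_human`,
#'   `t_chimp`, `t_orang` (default 0.01 each) and `kappa` (default 2).
#' @param tol Convergence tolerance on the log-likelihood. Default 1e-8.
#' @param max_iter Iteration cap for the bounded quasi-Newton optimizer.
#'   Default 500.
#' @param min_sites Minimum usable (gap/N-free) columns. Default 50.
#' @param fix_kappa Optional fixed kappa (e.g. 1 for the equal-rates limit);
#'   when given, kappa is not optimized.
#' @param equal_freqs Force equal base frequencies instead of empirical
#'   ones. Default `FALSE`.
#' @return An object of class `"hky_fit"`: `gene_id`, `t_human`, `t_chimp`,
#'   `t_orang` (substitutions/site), `kappa`, `base_freqs`, `loglik`,
#'   `n_sites`, `converged`.
#' @export
fit_hky85_trio <- function(alignment, gene_id = NULL, init = NULL, tol = 1e-8,
                           max_iter = 500L, min_sites = 50L, fix_kappa = NULL,
                           equal_freqs = FALSE) {
  if (inherits(alignment, "trio_alignment")) {
    if (is.null(gene_id)) gene_id <- alignment$gene_id
    rows <- alignment$rows
  } else {
    rows <- unlist(alignment)
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  pat <- trio_site_patterns(rows)
  if (pat$n_sites < min_sites) {
    stop("only ", pat$n_sites, " usable columns; need at least ", min_sites,
         call. = FALSE)
  }
  freqs <- if (equal_freqs) {
    rep(0.25, 4)
  } else {
    f <- pat$base_counts / sum(pat$base_counts)
    f <- pmax(f, 1e-6)
    f / sum(f)
  }
  init_full <- list(t_human = 0.01, t_chimp = 0.01, t_orang = 0.01, kappa = 2)
  init_full[names(init)] <- init
  t_lo <- 1e-9; t_hi <- 2; k_lo <- 0.05; k_hi <- 100
  free_kappa <- is.null(fix_kappa)

  par0 <- c(init_full$t_human, init_full$t_chimp, init_full$t_orang,
            if (free_kappa) init_full$kappa)
  nll <- function(par) {
    kap <- if (free_kappa) par[[4L]] else fix_kappa
    -hky_trio_loglik(par[[1L]], par[[2L]], par[[3L]], kap, freqs, pat)
  }
  opt <- stats::optim(
    par0, nll, method = "L-BFGS-B",
    lower = c(t_lo, t_lo, t_lo, if (free_kappa) k_lo),
    upper = c(t_hi, t_hi, t_hi, if (free_kappa) k_hi),
    control = list(maxit = max_iter, factr = max(tol / .Machine$double.eps, 1))
  )
  if (opt$convergence == 1L) {
    stop("HKY85 fit did not converge within ", max_iter, " iterations",
         call. = FALSE)
  }
  structure(
    list(
      gene_id = if (is.null(gene_id)) NA_character_ else as.character(gene_id),
      t_human = opt$par[[1L]], t_chimp = opt$par[[2L]], t_orang = opt$par[[3L]],
      kappa = if (free_kappa) opt$par[[4L]] else fix_kappa,
      base_freqs = stats::setNames(freqs, BASES),
      loglik = -opt$value, n_sites = pat$n_sites,
      converged = opt$convergence == 0L
    ),
    class = "hky_fit"
  )
}

#' @export
print.hky_fit <- function(x, ...) {
  cat("<hky_fit>", if (!is.na(x$gene_id)) x$gene_id, "\n")
  cat(sprintf("  t_human=%.5f  t_chimp=%.5f  t_orang=%.5f  kappa=%.3f\n",
              x$t_human, x$t_chimp, x$t_orang, x$kappa))
  cat(sprintf("  logLik=%.3f over %d sites\n", x$loglik, x$n_sites))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HKY85 trio fit into one row per parameter
#'
#' @param x An `hky_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy hky_fit
#' @export
tidy.hky_fit <- function(x, ...) {
  tibble::tibble(
    term = c("t_human", "t_chimp", "t_orang", "kappa"),
    estimate = c(x$t_human, x$t_chimp, x$t_orang, x$kappa)
  )
}

#' One-row model summary of an HKY85 trio fit
#'
#' @param x An `hky_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `gene_id`, branch lengths, `kappa`, `logLik`,
#'   `n_sites`, `converged`.
#' @method glance hky_fit
#' @export
glance.hky_fit <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, t_human = x$t_human, t_chimp = x$t_chimp,
    t_orang = x$t_orang, kappa = x$kappa, logLik = x$loglik,
    n_sites = x$n_sites, converged = x$converged
  )
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' The closed-form estimate `-(3/4) log(1 - (4/3) p)` with `p` the mismatch
#' fraction over gap/N-free columns; serves as the analytic limit of the
#' HKY85 fit at kappa = 1 with equal base frequencies.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @return Estimated substitutions per site.
#' @examples
#' jc_distance("ACGTACGTAC", "ACGTACGTAT")
#' @export
jc_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length", call. = FALSE)
  ca <- alignment_chars(toupper(a))
  cb <- alignment_chars(toupper(b))
  ok <- ca %in% BASES & cb %in% BASES
  if (!any(ok)) stop("no comparable columns", call. = FALSE)
  p <- mean(ca[ok] != cb[ok])
  if (p >= 0.75) {
    stop("saturation: mismatch fraction ", signif(p, 3), " >= 0.75", call. = FALSE)
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Summarize lineage-specific substitution rates over a gene set
#'
#' Applies the rate filter (genes whose human or chimpanzee branch exceeds
#' `max_lineage_rate`, default 0.1, are discarded) and reports the
#' per-lineage mean and standard deviation of the retained set, optionally
#' side by side with a genome-wide background set.
#'
#' @param estimates A data frame with columns `gene_id`, `t_human`,
#'   `t_chimp`, `t_orang` (e.g. `purrr::map_dfr(fits, glance)`), or a list
#'   of `hky_fit` objects.
#' @param background Optional second estimate set in the same form.
#' @param thresholds A [screen_thresholds()] object (or named list).
#' @return A tibble of class `"rate_summary"` with columns `set`, `lineage`,
#'   `mean_rate`, `sd_rate`, `n_retained`, `n_discarded`.
#' @export
summarize_rates <- function(estimates, background = NULL, thresholds = NULL) {
  th <- as_thresholds(thresholds)
  one_set <- function(est, set_name) {
    est <- as_rate_table(est)
    if (nrow(est) == 0L) stop("empty estimate set: ", set_name, call. = FALSE)
    keep <- est$t_human <= th$max_lineage_rate & est$t_chimp <= th$max_lineage_rate
    n_disc <- sum(!keep)
    est <- est[keep, , drop = FALSE]
    if (nrow(est) == 0L) {
      stop("all genes in set '", set_name, "' discarded by the rate filter",
           call. = FALSE)
    }
    tibble::tibble(
      set = set_name,
      lineage = c("human", "chimp", "orang"),
      mean_rate = c(mean(est$t_human), mean(est$t_chimp), mean(est$t_orang)),
      sd_rate = c(stats::sd(est$t_human), stats::sd(est$t_chimp),
                  stats::sd(est$t_orang)),
      n_retained = nrow(est),
      n_discarded = n_disc
    )
  }
  out <- one_set(estimates, "focal")
  if (!is.null(background)) out <- dplyr::bind_rows(out, one_set(background, "background"))
  class(out) <- c("rate_summary", class(out))
  out
}

as_rate_table <- function(est) {
  if (is.data.frame(est)) return(tibble::as_tibble(est))
  if (is.list(est) && all(vapply(est, inherits, logical(1), "hky_fit"))) {
    return(purrr::map_dfr(est, glance))
  }
  stop("estimates must be a data frame or a list of hky_fit objects", call. = FALSE)
}
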