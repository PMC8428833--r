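#' Pan- and core-genome rarefaction curves
#'
#' Estimates pan-genome size (genes present in at least one sampled
#' accession) and core-genome size (genes present in every sampled accession)
#' as a function of sample size, by repeated random sampling without
#' replacement. Each iteration draws one random accession order and evaluates
#' all prefix subsets of sizes 1..N, so within an iteration the pan count is
#' non-decreasing and the core count non-increasing by construction; a
#' size-n prefix of a uniform random permutation is a uniform random n-subset,
#' so per-size means estimate the same quantity as independent subsampling.
#'
#' @param matrix A [pav_matrix()] (or coercible).
#' @param n_iterations Number of random orders (default 100).
#' @param seed Optional seed.
#' @param keep_iterations If `TRUE`, attach the per-iteration pan/core count
#'   matrices (iterations x sizes) as attribute `"iterations"`.
#' @param exhaustive If `TRUE`, enumerate *all* accession orders instead of
#'   sampling (at most 7 accessions); per-size means are then exact subset
#'   expectations.
#' @return A `rarefaction_curves` tibble: `size`, `pan_mean`, `pan_min`,
#'   `pan_max`, `core_mean`, `core_min`, `core_max`, with `n_iterations` as an
#'   attribute.
#' @export
pan_core_curves <- function(matrix, n_iterations = 100L, seed = NULL,
                            keep_iterations = FALSE, exhaustive = FALSE) {
  if (n_iterations < 1L) abort("`n_iterations` must be at least 1.")
  m <- unclass(as_pav_matrix(matrix))
  G <- nrow(m); N <- ncol(m)
  perms <- NULL
  if (exhaustive) {
    if (N > 7L) abort("`exhaustive = TRUE` supports at most 7 accessions.")
    perms <- all_permutations(seq_len(N))
    n_iterations <- nrow(perms)
  }
  with_local_seed(seed, {
    pan <- matrix(0L, n_iterations, N)
    core <- matrix(0L, n_iterations, N)
    ever_present <- rowSums(m) > 0L
    always_present <- rowSums(m) == N
    for (it in seq_len(n_iterations)) {
      perm <- if (exhaustive) perms[it, ] else sample.int(N)
      a <- m[, perm, drop = FALSE]
      # Rank (within the permuted order) of the first presence / absence of
      # each gene; prefix counts follow by cumulative tally.
      first_present <- max.col(a, ties.method = "first")
      pan[it, ] <- cumsum(tabulate(first_present[ever_present], N))
      first_absent <- max.col(1L - a, ties.method = "first")
      lost <- cumsum(tabulate(first_absent[!always_present], N))
      core[it, ] <- G - lost
    }
    out <- tibble(
      size = seq_len(N),
      pan_mean = colMeans(pan), pan_min = apply(pan, 2, min),
      pan_max = apply(pan, 2, max),
      core_mean = colMeans(core), core_min = apply(core, 2, min),
      core_max = apply(core, 2, max)
    )
    attr(out, "n_iterations") <- as.integer(n_iterations)
    if (keep_iterations) {
      attr(out, "iterations") <- list(pan = pan, core = core)
    }
    class(out) <- c("rarefaction_curves", class(out))
    out
  })
}

#' Fit saturation models to rarefaction curves
#'
#' Fits the standard pan-genome saturation family on the mean curves:
#' a power law with offset for the pan curve, `P(n) = A * n^gamma + C`; a
#' decaying power law for per-accession new-gene discovery,
#' `Delta(n) = k * n^(-alpha)` (fit on successive differences of the mean pan
#' curve, log-log least squares); and an exponential decay with offset for
#' the core curve, `K(n) = B * exp(-n / tau) + Omega`. Openness verdicts
#' follow the classic criterion: the pan-genome is *closed* when new-gene
#' discovery decays faster than `1/n` (`alpha > 1`), and the core genome is
#' *open* when the fitted core curve is still dropping at the largest sample
#' size (|K(N) - K(N-1)| > 0.5 genes).
#'
#' @param curves A [pan_core_curves()] result (at least 4 distinct sizes).
#' @return A `saturation_fit` list with elements `pan`, `new_genes`, `core`
#'   (fitted parameters and residual sums of squares), `pan_verdict`
#'   (`"closed"`/`"open"`) and `core_verdict`. Non-converging fits yield `NA`
#'   parameters, a diagnostic message, and no verdict for the affected curve.
#' @export
fit_saturation <- function(curves) {
  if (length(unique(curves$size)) < 4L) {
    abort("Need at least 4 distinct sizes to fit saturation models.")
  }
  n <- curves$size
  pan <- curves$pan_mean
  core <- curves$core_mean

  fits <- list()

  # Pan power law with offset. A flat curve has A = 0 and indeterminate
  # gamma; report gamma = 0 directly.
  if (max(pan) - min(pan) < .Machine$double.eps^0.5) {
    fits$pan <- list(A = 0, gamma = 0, C = pan[1], rss = 0, converged = TRUE)
  } else {
    fits$pan <- try_nls(
      pan ~ A * n^gamma + C,
      data = list(pan = pan, n = n),
      start = list(A = pan[1] - max(pan), gamma = -0.5, C = max(pan)),
      params = c("A", "gamma", "C")
    )
  }

  # New-gene discovery power law on successive differences of the mean pan
  # curve; zero/negative differences (fully saturated tail) are excluded.
  dn <- diff(pan)
  sizes2 <- n[-1]
  pos <- dn > 0
  if (sum(pos) >= 2L) {
    lf <- stats::lm(log(dn[pos]) ~ log(sizes2[pos]))
    fits$new_genes <- list(
      k = exp(unname(stats::coef(lf)[1])),
      alpha = -unname(stats::coef(lf)[2]),
      rss = sum(stats::residuals(lf)^2),
      converged = TRUE
    )
  } else {
    # No (or one) positive increment: discovery has stopped entirely.
    fits$new_genes <- list(k = 0, alpha = Inf, rss = 0, converged = TRUE)
  }

  # Core exponential decay with offset.
  if (max(core) - min(core) < .Machine$double.eps^0.5) {
    fits$core <- list(B = 0, tau = 1, Omega = core[1], rss = 0,
                      converged = TRUE)
  } else {
    fits$core <- try_nls(
      core ~ B * exp(-n / tau) + Omega,
      data = list(core = core, n = n),
      start = list(B = core[1] - min(core), tau = max(n) / 4,
                   Omega = min(core)),
      params = c("B", "tau", "Omega")
    )
  }

  N <- max(n)
  pan_verdict <- if (isTRUE(fits$new_genes$converged)) {
    if (fits$new_genes$alpha > 1) "closed" else "open"
  } else NA_character_
  core_verdict <- if (isTRUE(fits$core$converged)) {
    kN <- fits$core$B * exp(-N / fits$core$tau) + fits$core$Omega
    kN1 <- fits$core$B * exp(-(N - 1) / fits$core$tau) + fits$core$Omega
    if (abs(kN - kN1) > 0.5) "open" else "closed"
  } else NA_character_

  structure(list(pan = fits$pan, new_genes = fits$new_genes,
                 core = fits$core, pan_verdict = pan_verdict,
                 core_verdict = core_verdict, n_max = N),
            class = "saturation_fit")
}

try_nls <- function(formula, data, start, params) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- as.list(setNames(rep(NA_real_, length(params)), params))
    out$rss <- NA_real_
    out$converged <- FALSE
    out$message <- conditionMessage(fit)
    return(out)
  }
  out <- as.list(stats::coef(fit))
  out$rss <- sum(stats::residuals(fit)^2)
  out$converged <- TRUE
  out
}

#' @describeIn fit_saturation tidy table of fitted parameters (one row per
#'   model term).
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  grab <- function(model, name) {
    ps <- model[setdiff(names(model), c("rss", "converged", "message"))]
    tibble(model = name, term = names(ps), estimate = unlist(ps))
  }
  bind_rows(grab(x$pan, "pan"), grab(x$new_genes, "new_genes"),
            grab(x$core, "core"))
}

#' @describeIn fit_saturation one-row summary with verdicts and fit quality.
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(
    pan_verdict = x$pan_verdict,
    core_verdict = x$core_verdict,
    alpha = x$new_genes$alpha,
    pan_rss = x$pan$rss,
    core_rss = x$core$rss
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit>\n")
  cat(sprintf("  pan-genome: %s (new-gene decay alpha = %.3f)\n",
              x$pan_verdict %||% "no verdict", x$new_genes$alpha))
  cat(sprintf("  core-genome: %s\n", x$core_verdict %||% "no verdict"))
  invisible(x)
}
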