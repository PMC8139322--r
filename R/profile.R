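#' Partition gene families into core, dispensable and strain-unique
#'
#' Classes are assigned by occupancy: families present in all genomes
#' are *core*, families present in exactly one genome are
#' *strain-unique*, everything else (two or more genomes, but not all)
#' is *dispensable*.  For a single-genome matrix the core rule takes
#' precedence ("shared by all strains"), so every family is core.
#'
#' @param matrix a [pa_matrix()]; every genome must carry at least one
#'   family
#' @return a `pan_partition`: per-family `classes`, class `counts` and
#'   percentage `fractions`, per-genome proportion of core genes among
#'   the genome's families (`core_proportion`), and per-genome
#'   strain-unique family counts (`unique_counts`)
#' @examples
#' m <- matrix(c(1,1,1, 1,1,0, 1,0,0), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("f1","f2","f3"), c("g1","g2","g3")))
#' partition(pa_matrix(m))
#' @export
partition <- function(matrix) {
  stopifnot(inherits(matrix, "pa_matrix"))
  counts <- matrix$counts
  if (!nrow(counts)) stop("empty matrix")
  empty <- colSums(counts > 0L) == 0L
  if (any(empty))
    stop("genome(s) with zero genes: ",
         paste(colnames(counts)[empty], collapse = ", "))
  n <- ncol(counts)
  occ <- rowSums(counts > 0L)
  classes <- ifelse(occ == n, "core",
                    ifelse(occ == 1L, "unique", "dispensable"))
  names(classes) <- rownames(counts)
  cls_counts <- c(core = sum(classes == "core"),
                  dispensable = sum(classes == "dispensable"),
                  unique = sum(classes == "unique"))
  pres <- counts > 0L
  core_prop <- colSums(pres[classes == "core", , drop = FALSE]) /
    colSums(pres)
  uniq_counts <- colSums(pres[classes == "unique", , drop = FALSE])
  structure(list(classes = classes, counts = cls_counts,
                 fractions = round(100 * cls_counts / sum(cls_counts), 1),
                 core_proportion = core_prop,
                 unique_counts = uniq_counts,
                 n_genomes = n, pan_size = nrow(counts)),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf("pan_partition: %d families over %d genomes\n",
              x$pan_size, x$n_genomes))
  cat(sprintf("  core %d (%.1f%%), dispensable %d (%.1f%%), unique %d (%.1f%%)\n",
              x$counts["core"], x$fractions["core"],
              x$counts["dispensable"], x$fractions["dispensable"],
              x$counts["unique"], x$fractions["unique"]))
  invisible(x)
}

#' Class fractions from printed pan-genome counts
#'
#' Arithmetic closure of a published partition: given pan, core and
#' dispensable counts, the strain-unique count is their difference and
#' all three class percentages follow.
#'
#' @param pan,core,dispensable family counts
#' @return named list: `unique` count and `core_pct`,
#'   `dispensable_pct`, `unique_pct` (percent of the pan-genome)
#' @examples
#' pan_fractions(9396, 2370, 3338)
#' @export
pan_fractions <- function(pan, core, dispensable) {
  if (core + dispensable > pan)
    stop("core + dispensable exceeds pan size")
  u <- pan - core - dispensable
  list(unique = u,
       core_pct = 100 * core / pan,
       dispensable_pct = 100 * dispensable / pan,
       unique_pct = 100 * u / pan)
}

#' Pan/core/new-gene rarefaction
#'
#' For each of `n_permutations` random genome orderings, genomes are
#' added one by one and the cumulative number of distinct families
#' (pan), shared families (core) and newly seen families (new) is
#' recorded.  Per permutation, pan(n) is non-decreasing, core(n)
#' non-increasing, new(n) = pan(n) - pan(n-1), and the endpoints equal
#' the partition totals.
#'
#' @param matrix a [pa_matrix()]
#' @param n_permutations number of random orderings (>= 1)
#' @param seed integer seed; trajectories are reproducible from it
#' @return a `pan_profile`: `n` (1..N), permutation-by-n matrices `pan`,
#'   `core`, `new`, their column means `pan_mean`, `core_mean`,
#'   `new_mean`, plus `n_permutations` and `seed`
#' @export
rarefaction <- function(matrix, n_permutations = 100, seed = 1) {
  stopifnot(inherits(matrix, "pa_matrix"), n_permutations >= 1)
  pres <- matrix$counts > 0L
  N <- ncol(pres)
  with_seed(derive_seed(seed, "rarefaction"), {
    pan <- core <- new <- matrix(0L, n_permutations, N)
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(N)
      traj <- rarefaction_one(pres, ord)
      pan[p, ] <- traj$pan; core[p, ] <- traj$core; new[p, ] <- traj$new
    }
    structure(list(n = seq_len(N), pan = pan, core = core, new = new,
                   pan_mean = colMeans(pan), core_mean = colMeans(core),
                   new_mean = colMeans(new),
                   n_permutations = n_permutations, seed = seed),
              class = "pan_profile")
  })
}

rarefaction_one <- function(pres, ord) {
  N <- length(ord)
  pan <- core <- new <- integer(N)
  cum_any <- cum_all <- pres[, ord[1]]
  pan[1] <- sum(cum_any); core[1] <- sum(cum_all); new[1] <- pan[1]
  for (i in seq_len(N - 1) + 1) {
    g <- pres[, ord[i]]
    cum_any <- cum_any | g
    cum_all <- cum_all & g
    pan[i] <- sum(cum_any); core[i] <- sum(cum_all)
    new[i] <- pan[i] - pan[i - 1]
  }
  list(pan = pan, core = core, new = new)
}

# ---- curve fitting ---------------------------------------------------

new_curve_fit <- function(model, params, r2, converged = TRUE,
                          undefined_r2 = FALSE) {
  structure(list(model = model, params = params, r_squared = r2,
                 converged = converged, undefined_r2 = undefined_r2,
                 open = if (model == "pan_power")
                   isTRUE(converged) && params[["gamma"]] > 0.01
                 else NA),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  eq <- switch(x$model,
    pan_power = sprintf("y = %.1f n^%.3f + %.1f",
                        x$params["A"], x$params["gamma"], x$params["C"]),
    core_expdecay = ,
    new_expdecay = sprintf("y = %.1f exp(-%.3f n) + %.1f",
                           x$params["A"], x$params["k"], x$params["omega"]))
  cat(sprintf("curve_fit [%s]: %s  (R2 = %.5f%s)\n", x$model, eq,
              x$r_squared,
              if (identical(x$open, TRUE)) ", open pan-genome" else ""))
  invisible(x)
}

r_squared <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # zero-variance convention: perfect fit of a constant is R2 = 1
    if (ss_res < 1e-12 * max(1, mean(y)^2)) list(r2 = 1, undef = FALSE)
    else list(r2 = NA_real_, undef = TRUE)
  } else list(r2 = 1 - ss_res / ss_tot, undef = FALSE)
}

# shared nonlinear least-squares driver: nlsLM with up to 5 jittered
# restarts from the documented initial values; never errors out, a
# non-convergent fit is returned flagged.
fit_nls <- function(formula, data, start, lower, upper, model) {
  jitter_seed <- derive_seed(1, paste0("fit-", model))
  fit <- NULL
  best_rss <- Inf
  with_seed(jitter_seed, {
    for (attempt in 0:5) {
      st <- start
      if (attempt > 0)
        st <- lapply(start, function(v) v * stats::runif(1, 0.5, 1.5) +
                       stats::runif(1, -0.01, 0.01))
      st <- mapply(function(v, lo, hi) min(max(v, lo), hi),
                   st, lower, upper, SIMPLIFY = FALSE)
      f <- tryCatch(
        minpack.lm::nlsLM(formula, data = data, start = st,
                          lower = unlist(lower), upper = unlist(upper),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) {
        rss <- sum(stats::resid(f)^2)
        if (rss < best_rss) { fit <- f; best_rss <- rss }
      }
    }
  })
  if (is.null(fit)) {
    params <- stats::setNames(rep(NA_real_, length(start)), names(start))
    return(new_curve_fit(model, params, NA_real_, converged = FALSE))
  }
  params <- stats::coef(fit)
  r2 <- r_squared(data$y, stats::predict(fit))
  new_curve_fit(model, params, r2$r2, converged = TRUE,
                undefined_r2 = r2$undef)
}

profile_xy <- function(x, n, which) {
  if (inherits(x, "pan_profile")) {
    y <- switch(which, pan = x$pan_mean, core = x$core_mean,
                new = x$new_mean)
    list(n = x$n, y = y)
  } else {
    y <- as.numeric(x)
    if (is.null(n)) n <- seq_along(y)
    list(n = n, y = y)
  }
}

#' Fit the power-law pan-genome model
#'
#' Least-squares fit of the three-parameter Heaps-law form
#' `y(n) = A * n^gamma + C` to the mean pan-genome trajectory.  A pan-
#' genome is called *open* when the fitted exponent `gamma` exceeds 0.01
#' (a small tolerance against numeric noise on closed trajectories).
#'
#' @param x a `pan_profile` from [rarefaction()] (its mean pan
#'   trajectory is used) or a numeric vector of pan sizes
#' @param n genome-count axis when `x` is a plain vector; defaults to
#'   `1..length(x)`
#' @return a `curve_fit` with `params["A"]`, `params["gamma"]`,
#'   `params["C"]`, `r_squared`, `converged` and the `open` flag
#' @export
fit_pan_curve <- function(x, n = NULL) {
  d <- profile_xy(x, n, "pan")
  if (length(unique(d$n)) < 4) stop("need >= 4 distinct n values")
  if (stats::sd(d$y) == 0)
    return(new_curve_fit("pan_power",
                         c(A = 0, gamma = 0, C = d$y[1]), 1))
  # C >= 0: the power-law offset is a baseline gene count, and an
  # unconstrained offset lets the optimiser drift into the degenerate
  # A*n^gamma ~ A*gamma*log(n) regime (A huge, gamma ~ 0, C large
  # negative), which misreports openness
  fit_nls(y ~ A * n^gamma + C,
          data = data.frame(n = d$n, y = d$y),
          start = list(A = diff(range(d$y)), gamma = 0.5,
                       C = max(min(d$y), 0)),
          lower = list(A = 0, gamma = 0, C = 0),
          upper = list(A = Inf, gamma = 2, C = Inf),
          model = "pan_power")
}

fit_decay <- function(d, model) {
  if (length(unique(d$n)) < 4) stop("need >= 4 distinct n values")
  if (stats::sd(d$y) == 0)
    return(new_curve_fit(model, c(A = 0, k = 0, omega = d$y[1]), 1))
  fit_nls(y ~ A * exp(-k * n) + omega,
          data = data.frame(n = d$n, y = d$y),
          start = list(A = diff(range(d$y)), k = 0.1, omega = min(d$y)),
          lower = list(A = -Inf, k = 0, omega = 0),
          upper = list(A = Inf, k = 5, omega = Inf),
          model = model)
}

#' Fit the exponential-decay core-genome model
#'
#' Least-squares fit of `c(n) = A * exp(-k * n) + omega` to the mean
#' core-genome trajectory; `omega` is the extrapolated asymptotic core
#' size.
#'
#' @inheritParams fit_pan_curve
#' @return a `curve_fit` with `params["A"]`, `params["k"]`,
#'   `params["omega"]`
#' @export
fit_core_curve <- function(x, n = NULL) {
  fit_decay(profile_xy(x, n, "core"), "core_expdecay")
}

#' Fit the exponential-decay new-gene model
#'
#' Same functional form as [fit_core_curve()], fitted to the mean
#' number of new families contributed by the n-th genome, for n >= 2
#' (the first genome contributes its whole gene set and is excluded).
#' A positive fitted asymptote `omega` indicates that new genes keep
#' arriving as genomes are added -- the signature of an open pan-genome.
#'
#' @inheritParams fit_pan_curve
#' @export
fit_new_gene_curve <- function(x, n = NULL) {
  d <- profile_xy(x, n, "new")
  if (inherits(x, "pan_profile")) {
    keep <- d$n >= 2
    d <- list(n = d$n[keep], y = d$y[keep])
  }
  fit_decay(d, "new_expdecay")
}

#' COG composition of core versus non-core families
#'
#' For every COG category: the percentage of core families and of
#' non-core (dispensable + strain-unique) families annotated with it,
#' and the core/non-core ratio of those percentages.  Families absent
#' from `cog_table` are counted as `"unknown"`.
#'
#' @param part a [partition()] result
#' @param cog_table `data.frame(family, category)`
#' @return `data.frame(category, core_pct, noncore_pct, ratio)`, sorted
#'   by decreasing ratio
#' @export
cog_class_contrast <- function(part, cog_table) {
  stopifnot(inherits(part, "pan_partition"))
  cat_of <- stats::setNames(cog_table$category, cog_table$family)
  fam <- names(part$classes)
  cats <- ifelse(fam %in% names(cat_of), cat_of[fam], "unknown")
  is_core <- part$classes == "core"
  all_cats <- sort(unique(cats))
  core_n <- table(factor(cats[is_core], levels = all_cats))
  non_n <- table(factor(cats[!is_core], levels = all_cats))
  core_pct <- 100 * as.numeric(core_n) / max(1, sum(is_core))
  non_pct <- 100 * as.numeric(non_n) / max(1, sum(!is_core))
  out <- data.frame(category = all_cats, core_pct = core_pct,
                    noncore_pct = non_pct,
                    ratio = ifelse(non_pct > 0, core_pct / non_pct,
                                   ifelse(core_pct > 0, Inf, NA_real_)))
  out[order(-out$ratio), , drop = FALSE]
}
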