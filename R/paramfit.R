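term_key <- function(terms) {
  idx <- cbind(terms$i, terms$j, terms$k, terms$l)
  vapply(seq_len(nrow(terms)), function(r) {
    paste(c(terms$kind[r], idx[r, !is.na(idx[r, ])]), collapse = "_")
  }, character(1))
}

FITTED_KINDS <- c("bond", "angle", "dihedral_proper", "dihedral_improper")

#' Compute target distributions for every fitted bonded term
#'
#' Measures each bond, angle and dihedral of `topology` over `traj`
#' (typically a pseudo-CG mapped atomistic trajectory) and histograms it.
#' Constraints and restraints are skipped. The result feeds
#' [refine_parameters()] as its `targets` argument.
#'
#' @param traj a `cg_traj`.
#' @param topology an `sma_topology` whose bead indices match `traj` rows.
#' @param bin_width optional named vector overriding bin widths per variable
#'   kind, e.g. `c(length = 0.002, angle = 1, dihedral = 2)`.
#' @return A named list of `sma_distribution` objects keyed by
#'   `kind_i_j[_k[_l]]`.
#' @export
compute_bonded_targets <- function(traj, topology, bin_width = NULL) {
  t <- topology$terms
  fit <- t[t$kind %in% FITTED_KINDS, ]
  keys <- term_key(fit)
  out <- purrr::map(seq_len(nrow(fit)), function(r) {
    row <- fit[r, ]
    bw <- if (!is.null(bin_width)) {
      unname(bin_width[term_variable(row$kind)])
    } else NULL
    compute_distribution(traj, row, bin_width = bw)
  })
  stats::setNames(out, keys)
}

dist_cos_moments <- function(d) {
  p <- dist_probs(d)
  cs <- cos(d$mid * pi / 180)
  m <- sum(p * cs)
  list(mean = m, var = sum(p * cs^2) - m^2)
}

dist_well_depth <- function(d, kT) {
  p <- dist_probs(d)
  i <- p > 0
  u <- -kT * log(p[i])
  max(u) - min(u)
}

# The sampled distribution of u = cos(theta) under a cosine-harmonic angle
# is exactly a Gaussian truncated to [-1, 1] (the sin(theta) Jacobian is
# flat in u). Invert measured (mean, var) of u to the untruncated
# parameters (u0, s2) by fixed-point iteration on the truncated-normal
# moment formulas; without this correction, force constants of wide or
# near-linear angles are systematically underestimated.
trunc_cos_solve <- function(m, v, iters = 60) {
  u0 <- m; s2 <- v
  for (it in seq_len(iters)) {
    s <- sqrt(s2)
    a <- (-1 - u0) / s; b <- (1 - u0) / s
    Z <- max(stats::pnorm(b) - stats::pnorm(a), 1e-12)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    mean_t <- u0 + s * (da - db) / Z
    var_t <- s2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    u0 <- u0 + (m - mean_t)
    s2 <- s2 * v / max(var_t, 1e-12)
    if (abs(mean_t - m) < 1e-12 && abs(var_t / v - 1) < 1e-12) break
  }
  list(u0 = min(0.9999, max(-0.9999, u0)), s2 = s2)
}

# Weighted LS amplitude of k (1 + cos(n phi - phase)) fitted to the
# inverted potential of a dihedral distribution, with n fixed: a robust
# well-depth estimate (half the fitted peak-to-peak) for the k update.
fit_dihedral_amplitude <- function(d, n, kT) {
  p <- dist_probs(d)
  keep <- p > 0
  u <- -kT * log(p[keep])
  phi <- d$mid[keep] * pi / 180
  X <- cbind(1, cos(n * phi), sin(n * phi))
  cf <- stats::lm.wfit(X, u, p[keep])$coefficients
  sqrt(cf[2]^2 + cf[3]^2)
}

# Count modes as maximal runs of smoothed density above a fraction of the
# peak, separated by dips below it; robust to the flat ties a median
# smoother produces.
count_modes <- function(d, frac = 0.2) {
  y <- stats::runmed(d$density, k = min(7, 2 * (nrow(d) %/% 2) - 1))
  high <- y >= frac * max(y)
  r <- rle(high)
  sum(r$values)
}

#' Direct Boltzmann inversion of a bonded distribution
#'
#' Initial-guess parameters from a target distribution at temperature `T`:
#' bonds take `b0 = mean`, `kb = kBT / var(b)`; angles (cosine-harmonic form)
#' take `cos(theta0) = mean(cos theta)`, `ka = kBT / var(cos theta)`;
#' proper dihedrals are fitted by weighted least squares of
#' `kphi (1 + cos(n phi - phi_s))` to the inverted potential
#' `-kBT ln p(phi)` over candidate multiplicities `n = 1, 2, 3` (best
#' residual wins); improper dihedrals take the circular mean and
#' `kxi = kBT / var(xi)`. A near-delta bond distribution (sd below
#' `constraint_sd`) is promoted to a constraint at the distribution mean,
#' the same convention used for the aromatic ring beads. A multimodal bond
#' distribution is an error.
#'
#' @param dist an `sma_distribution`.
#' @param kind term kind the distribution belongs to.
#' @param temperature K.
#' @param constraint_sd bond sd (nm) below which a constraint is suggested.
#' @return One-row tibble with `kind`, `c0`, `c1`, `c2` in the topology
#'   `terms` convention.
#' @export
boltzmann_invert <- function(dist, kind, temperature = 310,
                             constraint_sd = 0.005) {
  kT <- KB * temperature
  variable <- term_variable(kind)
  row <- function(kind, c0, c1 = NA_real_, c2 = NA_real_) {
    tibble::tibble(kind = kind, c0 = c0, c1 = c1, c2 = c2)
  }
  if (variable == "length") {
    m <- dist_mean(dist); v <- dist_var(dist)
    if (sqrt(v) < constraint_sd) {
      message("near-rigid bond (sd = ", signif(sqrt(v), 3),
              " nm): constraint recommended")
      return(row("constraint", m))
    }
    if (count_modes(dist) > 1) {
      stop("multimodal bond distribution cannot be Boltzmann-inverted",
           call. = FALSE)
    }
    return(row("bond", m, kT / v))
  }
  if (variable == "angle") {
    mm <- dist_cos_moments(dist)
    theta0 <- acos(pmin(1, pmax(-1, mm$mean))) * 180 / pi
    return(row("angle", theta0, kT / mm$var))
  }
  if (kind == "dihedral_improper") {
    p <- dist_probs(dist)
    rad <- dist$mid * pi / 180
    xi0 <- atan2(sum(p * sin(rad)), sum(p * cos(rad)))
    dxi <- (rad - xi0 + pi) %% (2 * pi) - pi
    v <- sum(p * dxi^2) - sum(p * dxi)^2
    return(row("dihedral_improper", xi0 * 180 / pi, kT / v))
  }
  # proper dihedral: weighted LS fit of the inverted potential
  p <- dist_probs(dist)
  keep <- p > 0
  u <- -kT * log(p[keep])
  phi <- dist$mid[keep] * pi / 180
  w <- p[keep]
  best <- NULL
  for (n in 1:3) {
    X <- cbind(1, cos(n * phi), sin(n * phi))
    fitlm <- stats::lm.wfit(X, u, w)
    rss <- sum(w * fitlm$residuals^2)
    if (is.null(best) || rss < best$rss) {
      a <- fitlm$coefficients[2]; b <- fitlm$coefficients[3]
      best <- list(rss = rss, n = n, kphi = sqrt(a^2 + b^2),
                   phase = atan2(b, a) * 180 / pi)
    }
  }
  # U = C + kphi cos(n phi - phi_s) matches kphi (1 + cos(...)) up to C
  row("dihedral_proper", best$phase, best$kphi, best$n)
}

#' Iteratively refine bonded parameters against target distributions
#'
#' Alternates between sampling the current model with
#' [sample_bonded_ensemble()] and moment-matching updates, until the
#' largest per-term Jensen-Shannon divergence between sampled and target
#' distributions drops to `tol` or `max_iters` is reached. Updates:
#' `kb <- kb (var_sim / var_target)`, `b0 <- b0 + (mean_target - mean_sim)`
#' for bonds (the same on `cos theta` for angles and on the wrapped angle
#' for impropers); proper-dihedral amplitudes are rescaled by the ratio of
#' inverted-potential well depths. If the metric rises for three
#' consecutive iterations the update step is halved; if it keeps rising the
#' fit stops with a non-convergence flag. The best model seen is always the
#' one returned. Bond targets that are nearly rigid (sd < 0.005 nm) are
#' promoted to constraints up front.
#'
#' @param topology starting `sma_topology` (initial parameter guess).
#' @param targets named list of `sma_distribution` targets keyed as in
#'   [compute_bonded_targets()]; an unnamed list is matched positionally to
#'   the fitted terms.
#' @param max_iters maximum refinement iterations.
#' @param tol convergence tolerance on the maximum per-term JSD (base 2).
#' @param temperature K.
#' @param seed base RNG seed; iteration `i` samples with `seed + i`.
#' @param n_steps Monte Carlo steps per iteration.
#' @param bin_width optional named per-variable bin-width overrides for the
#'   sampled distributions (see [compute_bonded_targets()]); coarser bins
#'   lower the sampling-noise floor of the metric.
#' @return An `sma_fit`: `topology` (best model), `terms` (per-term tibble
#'   with final parameters and metrics), `history`, `converged`,
#'   `iterations`.
#' @export
refine_parameters <- function(topology, targets, max_iters = 20, tol = 0.02,
                              temperature = 310, seed = 1, n_steps = 2e5,
                              bin_width = NULL) {
  validate_topology(topology)
  terms <- topology$terms
  fit_rows <- which(terms$kind %in% FITTED_KINDS)
  keys <- term_key(terms[fit_rows, ])
  if (is.null(names(targets))) {
    if (length(targets) != length(fit_rows)) {
      stop("need one target per fitted term (", length(fit_rows), ")",
           call. = FALSE)
    }
    names(targets) <- keys
  }
  missing <- setdiff(keys, names(targets))
  if (length(missing)) {
    stop("missing target(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  # promote near-rigid bond targets to constraints before fitting
  for (r in fit_rows) {
    key <- term_key(terms[r, ])
    if (terms$kind[r] == "bond") {
      tg <- targets[[key]]
      if (sqrt(dist_var(tg)) < 0.005) {
        terms$kind[r] <- "constraint"
        terms$c0[r] <- dist_mean(tg)
        terms$c1[r] <- NA_real_
      }
    }
  }
  topology$terms <- terms
  fit_rows <- which(terms$kind %in% FITTED_KINDS)
  keys <- term_key(terms[fit_rows, ])
  if (length(fit_rows) == 0) {
    # everything was promoted to constraints: nothing left to fit
    return(structure(
      list(topology = topology,
           terms = tibble::tibble(term = character(), kind = character(),
                                  i = integer(), j = integer(), k = integer(),
                                  l = integer(), c0 = double(), c1 = double(),
                                  c2 = double(), jsd = double()),
           history = tibble::tibble(iteration = integer(),
                                    metric_max = double(),
                                    metric_mean = double(),
                                    damping = double()),
           converged = TRUE, iterations = 0L, best_iteration = 0L,
           tol = tol, temperature = temperature, n_steps = n_steps),
      class = "sma_fit"
    ))
  }

  kT <- KB * temperature
  cur <- topology
  damping <- 1
  halved <- FALSE
  rising <- 0L
  best <- NULL
  prev_metric <- Inf
  history <- list()
  converged <- FALSE
  iterations <- 0L

  target_moments <- purrr::map(seq_along(keys), function(kidx) {
    tg <- targets[[keys[kidx]]]
    kind <- terms$kind[fit_rows[kidx]]
    out <- list(mean = dist_mean(tg), var = dist_var(tg))
    if (kind == "angle") {
      mm <- dist_cos_moments(tg)
      out$cos <- trunc_cos_solve(mm$mean, mm$var)
    }
    if (kind == "dihedral_proper") {
      out$amp <- fit_dihedral_amplitude(tg, terms$c2[fit_rows[kidx]], kT)
    }
    out
  })

  for (iter in 0:max_iters) {
    traj <- sample_bonded_ensemble(cur, temperature = temperature,
                                   n_steps = n_steps, seed = seed + iter)
    sims <- purrr::map(fit_rows, function(r) {
      bw <- if (!is.null(bin_width)) {
        unname(bin_width[term_variable(cur$terms$kind[r])])
      } else NULL
      compute_distribution(traj, cur$terms[r, ], bin_width = bw)
    })
    names(sims) <- keys
    metrics <- purrr::map2_dbl(sims, targets[keys], distribution_distance)
    metric_max <- max(metrics)
    history[[length(history) + 1L]] <- tibble::tibble(
      iteration = iter, metric_max = metric_max,
      metric_mean = mean(metrics), damping = damping
    )
    if (is.null(best) || metric_max < best$metric_max) {
      best <- list(topology = cur, metric_max = metric_max,
                   metrics = metrics, iteration = iter)
    }
    iterations <- iter
    if (metric_max <= tol) { converged <- TRUE; break }
    if (iter == max_iters) break
    if (metric_max > prev_metric) {
      rising <- rising + 1L
      if (rising >= 3L) {
        if (!halved) {
          damping <- damping / 2
          halved <- TRUE
          rising <- 0L
        } else {
          break  # still diverging: give up, keep best-seen model
        }
      }
    } else rising <- 0L
    prev_metric <- metric_max

    # moment-matching updates
    t2 <- cur$terms
    for (kidx in seq_along(fit_rows)) {
      r <- fit_rows[kidx]
      tm <- target_moments[[kidx]]
      sim <- sims[[kidx]]
      kind <- t2$kind[r]
      if (kind == "bond") {
        ms <- dist_mean(sim); vs <- dist_var(sim)
        t2$c0[r] <- t2$c0[r] + damping * (tm$mean - ms)
        if (tm$var > 0 && vs > 0) {
          t2$c1[r] <- t2$c1[r] * (vs / tm$var)^damping
        }
      } else if (kind == "angle") {
        smm <- dist_cos_moments(sim)
        sm <- trunc_cos_solve(smm$mean, smm$var)
        c0 <- cos(t2$c0[r] * pi / 180) + damping * (tm$cos$u0 - sm$u0)
        t2$c0[r] <- acos(pmin(0.9999, pmax(-0.9999, c0))) * 180 / pi
        if (tm$cos$s2 > 0 && sm$s2 > 0) {
          t2$c1[r] <- t2$c1[r] * (sm$s2 / tm$cos$s2)^damping
        }
      } else if (kind == "dihedral_improper") {
        rad_s <- sim$mid * pi / 180; p <- dist_probs(sim)
        mu_s <- atan2(sum(p * sin(rad_s)), sum(p * cos(rad_s))) * 180 / pi
        dxi <- (sim$mid - mu_s + 180) %% 360 - 180
        vs <- (sum(p * (dxi * pi / 180)^2) - sum(p * dxi * pi / 180)^2)
        tg <- targets[[keys[kidx]]]
        rad_t <- tg$mid * pi / 180; pt <- dist_probs(tg)
        mu_t <- atan2(sum(pt * sin(rad_t)), sum(pt * cos(rad_t))) * 180 / pi
        dxt <- (tg$mid - mu_t + 180) %% 360 - 180
        vt <- (sum(pt * (dxt * pi / 180)^2) - sum(pt * dxt * pi / 180)^2)
        dmu <- (mu_t - mu_s + 180) %% 360 - 180
        t2$c0[r] <- ((t2$c0[r] + damping * dmu + 180) %% 360) - 180
        if (vt > 0 && vs > 0) t2$c1[r] <- t2$c1[r] * (vs / vt)^damping
      } else if (kind == "dihedral_proper") {
        ds <- fit_dihedral_amplitude(sim, t2$c2[r], kT)
        if (tm$amp > 0 && ds > 0) {
          t2$c1[r] <- t2$c1[r] * (tm$amp / ds)^damping
        }
      }
    }
    cur$terms <- t2
  }

  final <- best$topology
  ft <- final$terms[fit_rows, ]
  out_terms <- dplyr::mutate(ft,
    term = keys, jsd = unname(unlist(best$metrics)), .before = 1
  )
  structure(
    list(topology = final, terms = tibble::as_tibble(out_terms),
         history = dplyr::bind_rows(history), converged = converged,
         iterations = iterations, best_iteration = best$iteration,
         tol = tol, temperature = temperature, n_steps = n_steps),
    class = "sma_fit"
  )
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf(
    "<sma_fit> %s after %d iteration(s); best max JSD = %.4g (tol %.3g)\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    max(x$terms$jsd), x$tol
  ))
  print(x$terms)
  invisible(x)
}

#' Tidy a refined bonded-parameter fit
#'
#' @param x an `sma_fit` from [refine_parameters()].
#' @param ... unused.
#' @return One row per fitted term: key, kind, bead indices, final
#'   parameters (`c0`, `c1`, `c2`) and the final Jensen-Shannon divergence.
#' @export
tidy.sma_fit <- function(x, ...) x$terms

#' @rdname tidy.sma_fit
#' @return `glance()`: a one-row summary (convergence flag, iterations,
#'   best metric, tolerance, temperature, steps per iteration).
#' @export
glance.sma_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, iterations = x$iterations,
    best_iteration = x$best_iteration, metric_max = max(x$terms$jsd),
    tol = x$tol, temperature = x$temperature, n_steps = x$n_steps
  )
}
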