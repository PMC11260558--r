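#' Joint site-frequency spectrum container
#'
#' A two-population SFS: an `(n1 + 1) x (n2 + 1)` grid whose `(i, j)` entry
#' holds the (expected) number of sites with alternate-allele counts `i` in
#' population 1 and `j` in population 2. A logical mask marks cells excluded
#' from likelihoods (the absent/fixed corners, and the redundant half after
#' folding).
#'
#' @param counts numeric matrix, `(n1 + 1) x (n2 + 1)`, entries >= 0.
#' @param n1,n2 haplotype sample sizes.
#' @param folded is the spectrum folded to minor-allele orientation?
#' @param mask logical matrix, `TRUE` = excluded; defaults to the corners.
#' @return an object of class `joint_sfs`.
#' @export
new_joint_sfs <- function(counts, n1, n2, folded = FALSE, mask = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == n1 + 1, ncol(counts) == n2 + 1)
  if (any(counts < -1e-9)) abort("SFS entries must be >= 0.")
  if (is.null(mask)) {
    mask <- matrix(FALSE, n1 + 1, n2 + 1)
    mask[1, 1] <- TRUE
    mask[n1 + 1, n2 + 1] <- TRUE
  }
  dimnames(counts) <- list(0:n1, 0:n2)
  dimnames(mask) <- dimnames(counts)
  structure(
    list(counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
         folded = folded, mask = mask),
    class = "joint_sfs"
  )
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf(
    "<joint_sfs> (%d, %d) haplotypes, %s, %.4g sites in unmasked cells\n",
    x$n1, x$n2, if (x$folded) "folded" else "unfolded",
    sum(x$counts[!x$mask])
  ))
  invisible(x)
}

#' Fold a joint SFS to minor-allele orientation
#'
#' Combines each cell `(i, j)` with its complement `(n1 - i, n2 - j)`. The
#' representative cell is the one with the smaller total allele count
#' (ties: the smaller `i`; self-complementary cells stay put). Cells vacated
#' by folding are masked, as is the `(0, 0)` corner.
#'
#' @param sfs a [new_joint_sfs] object.
#' @return the folded `joint_sfs` (folding an already folded spectrum is a
#'   no-op).
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) return(sfs)
  n1 <- sfs$n1; n2 <- sfs$n2
  m <- sfs$counts
  out <- matrix(0, n1 + 1, n2 + 1)
  keep <- matrix(FALSE, n1 + 1, n2 + 1)
  for (i in 0:n1) {
    for (j in 0:n2) {
      ip <- n1 - i; jp <- n2 - j
      rep_here <- (i + j < ip + jp) || (i + j == ip + jp && i <= ip)
      if (rep_here) {
        out[i + 1, j + 1] <- out[i + 1, j + 1] + m[i + 1, j + 1]
        keep[i + 1, j + 1] <- TRUE
        if (!(i == ip && j == jp)) {
          out[i + 1, j + 1] <- out[i + 1, j + 1] + m[ip + 1, jp + 1]
        }
      }
    }
  }
  mask <- !keep
  mask[1, 1] <- TRUE
  new_joint_sfs(out, n1, n2, folded = TRUE, mask = mask)
}

#' Tabulate the joint SFS from genotypes
#'
#' Accumulates per-site joint alternate-allele counts over two populations.
#' Sites with missing genotypes are hypergeometrically projected down to the
#' target sample sizes (the expected contribution of the called alleles);
#' sites with fewer called chromosomes than the target in either population
#' are skipped and counted in the `n_skipped` attribute.
#'
#' @param gm a [gmat].
#' @param pops per-sample population labels (two populations used, sorted
#'   order defines axis 1 and 2).
#' @param n1,n2 target haplotype sample sizes (default: all chromosomes of
#'   each population).
#' @param fold fold to minor-allele orientation (the default; polarisation
#'   against an outgroup is rarely available for these data).
#' @return a `joint_sfs`.
#' @export
joint_sfs <- function(gm, pops, n1 = NULL, n2 = NULL, fold = TRUE) {
  pops <- as.character(pops)
  lv <- sort(unique(pops[!is.na(pops)]))
  if (length(lv) != 2) abort("`pops` must contain exactly two populations.")
  c1 <- allele_counts(gm, !is.na(pops) & pops == lv[1])
  c2 <- allele_counts(gm, !is.na(pops) & pops == lv[2])
  if (is.null(n1)) n1 <- 2 * sum(pops == lv[1], na.rm = TRUE)
  if (is.null(n2)) n2 <- 2 * sum(pops == lv[2], na.rm = TRUE)
  usable <- c1$n_chr >= n1 & c2$n_chr >= n2
  m <- matrix(0, n1 + 1, n2 + 1)
  for (l in which(usable)) {
    w1 <- dhyper(0:n1, c1$alt[l], c1$n_chr[l] - c1$alt[l], n1)
    w2 <- dhyper(0:n2, c2$alt[l], c2$n_chr[l] - c2$alt[l], n2)
    m <- m + outer(w1, w2)
  }
  out <- new_joint_sfs(m, n1, n2, folded = FALSE)
  attr(out, "n_skipped") <- sum(!usable)
  attr(out, "pops") <- lv
  if (fold) out <- fold_sfs(out)
  out
}

#' Project a joint SFS to smaller sample sizes
#'
#' Hypergeometric down-sampling of each axis, the standard device for
#' rescuing sites lost to missing data. Mass landing in the absent/fixed
#' corners after projection is masked but retained in the grid.
#'
#' @param sfs an unfolded `joint_sfs`.
#' @param n1,n2 target sizes, `<=` the current sizes.
#' @return the projected `joint_sfs`.
#' @export
project_sfs <- function(sfs, n1, n2) {
  if (sfs$folded) abort("project before folding, not after.")
  if (n1 > sfs$n1 || n2 > sfs$n2) {
    abort("projection must go down: target sizes exceed current sizes.")
  }
  p1 <- outer(0:sfs$n1, 0:n1, function(i, j) dhyper(j, i, sfs$n1 - i, n1))
  p2 <- outer(0:sfs$n2, 0:n2, function(i, j) dhyper(j, i, sfs$n2 - i, n2))
  new_joint_sfs(t(p1) %*% sfs$counts %*% p2, n1, n2, folded = FALSE)
}

# M^g and sum_{t=1..g} M^t by binary exponentiation
mat_pow_sum <- function(m, g) {
  if (g == 0) {
    return(list(P = diag(nrow(m)), S = matrix(0, nrow(m), nrow(m))))
  }
  if (g %% 2 == 1) {
    h <- mat_pow_sum(m, g - 1)
    list(P = h$P %*% m, S = m %*% (diag(nrow(m)) + h$S))
  } else {
    h <- mat_pow_sum(m, g / 2)
    list(P = h$P %*% h$P, S = h$S + h$P %*% h$S)
  }
}

# Wright-Fisher binomial transition matrix on a grid of K chromosomes
wf_matrix <- function(K) {
  m <- outer(0:K, 0:K, function(a, b) dbinom(b, K, a / K))
  leak <- max(abs(rowSums(m) - 1))
  if (leak > 1e-6) {
    abort(sprintf("Wright-Fisher transition matrix leaks mass (%.2g).", leak))
  }
  m
}

#' Expected joint SFS under a two-population divergence model
#'
#' Deterministic expected spectrum per unit `theta` (`theta = 4 N_ref mu L`)
#' computed on a discrete Wright-Fisher frequency grid of `n_grid` diploids
#' for the reference (ancestral) population.
#'
#' `split_nomig`: ancestral standing variation at neutral equilibrium
#' (density `1/i` over grid counts) enters each daughter by a binomial
#' founding draw; each daughter's frequency then evolves independently by a
#' binomial Wright-Fisher transition matrix on a grid scaled by its relative
#' size `nu` for `T` (units of `2 N_ref` generations); post-split mutations
#' inject singleton mass each generation at rate `nu/2` per population and
#' contribute marginal-axis mass. Samples of `n1`, `n2` haplotypes are drawn
#' binomially from the grid frequencies, and folding (optional) is applied
#' last.
#'
#' `split_mig`: the joint frequency distribution over both daughter grids is
#' propagated generation by generation with migration mixing
#' (`m12`, `m21` are scaled rates `2 N_ref m`, the per-generation migrant
#' fraction times `2 N_ref`), a coarse but fully joint treatment; it reduces
#' to `split_nomig` as the migration rates go to zero.
#'
#' @param model `"split_nomig"` or `"split_mig"`.
#' @param params named list/vector: `nu1`, `nu2` (relative sizes,
#'   `nu1 + nu2 <= 1`), `T` (divergence time in `2 N_ref` generations), and
#'   for `split_mig` also `m12`, `m21`.
#' @param n1,n2 haplotype sample sizes.
#' @param n_grid grid (reference) population size in diploids.
#' @param fold fold the spectrum (default `TRUE`).
#' @param extrapolate Richardson-extrapolate over grid sizes `n_grid` and
#'   `1.5 * n_grid` to cancel the leading `O(1/grid)` discretisation error
#'   (costs a second evaluation; most visible in singleton cells).
#' @return a `joint_sfs` of expected counts per unit theta.
#' @export
expected_joint_sfs <- function(model = c("split_nomig", "split_mig"), params,
                               n1, n2, n_grid = 100, fold = TRUE,
                               extrapolate = FALSE) {
  if (extrapolate) {
    lo <- expected_joint_sfs(model, params, n1, n2, n_grid = n_grid,
                             fold = FALSE, extrapolate = FALSE)
    hi <- expected_joint_sfs(model, params, n1, n2,
                             n_grid = as.integer(round(1.5 * n_grid)),
                             fold = FALSE, extrapolate = FALSE)
    s <- new_joint_sfs(pmax(3 * hi$counts - 2 * lo$counts, 0), n1, n2,
                       folded = FALSE)
    if (fold) s <- fold_sfs(s)
    return(s)
  }
  model <- match.arg(model)
  params <- as.list(params)
  nu1 <- params$nu1; nu2 <- params$nu2; T <- params$T
  if (is.null(nu1) || is.null(nu2) || is.null(T)) {
    abort("`params` must contain nu1, nu2 and T.")
  }
  if (nu1 + nu2 > 1 + 1e-9) abort("`nu1 + nu2` must not exceed 1.")
  if (T < 0) abort("`T` must be >= 0.")
  K <- 2L * n_grid
  if (max(n1, n2) > K) abort("grid too small for the sample sizes.")
  # both backends interpolate linearly in the (integer) daughter grid sizes
  # and generation counts, so the likelihood is continuous in nu and T
  if (model == "split_nomig") {
    out <- sfs_nomig(K, nu1, nu2, T, n1, n2)
  } else {
    out <- sfs_mig(K, nu1, nu2, T, n1, n2,
                   (params$m12 %||% 0) / K, (params$m21 %||% 0) / K)
  }
  s <- new_joint_sfs(out, n1, n2, folded = FALSE)
  if (fold) s <- fold_sfs(s)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integer grid sizes bracketing K * nu, with the interpolation weight
grid_bracket <- function(K, nu) {
  ke <- K * nu
  lo <- max(4L, as.integer(floor(ke)))
  list(lo = lo, hi = lo + 1L, w = max(0, min(1, ke - lo)))
}

# Joint founding-count mass from ancestral standing variation (density
# theta/x, unit theta): the integral over the ancestral frequency is exact,
# int x^(j1+j2-1) (1-x)^(K1+K2-j1-j2) dx = Beta(j1+j2, K1+K2-j1-j2+1).
standing_joint <- function(K1, K2) {
  j1 <- 0:K1
  j2 <- 0:K2
  s <- outer(j1, j2, function(a, b) {
    exp(lchoose(K1, a) + lchoose(K2, b) + lbeta(a + b, K1 + K2 - a - b + 1))
  })
  s[1, 1] <- 0  # alleles lost in both founders never segregate
  s
}

sfs_nomig <- function(K, nu1, nu2, T, n1, n2) {
  g_lo <- as.integer(floor(T * K))
  wg <- T * K - g_lo
  per_pop_at <- function(Kk, nuk, nk) {
    wf <- wf_matrix(Kk)
    ps <- mat_pow_sum(wf, g_lo)
    if (wg > 1e-9) {
      p_hi <- ps$P %*% wf
      pw <- (1 - wg) * ps$P + wg * p_hi
      sw <- (1 - wg) * ps$S + wg * (ps$S + p_hi)
    } else {
      pw <- ps$P
      sw <- ps$S
    }
    smp <- outer(0:Kk, 0:nk, function(a, j) dbinom(j, nk, a / Kk))
    list(
      cond = pw %*% smp,                        # founding count -> sample
      new_mut = drop((nuk / 2) * (sw[2, ] %*% smp))
    )
  }
  br1 <- grid_bracket(K, nu1)
  br2 <- grid_bracket(K, nu2)
  p1 <- list(lo = per_pop_at(br1$lo, nu1, n1),
             hi = if (br1$w > 1e-9) per_pop_at(br1$hi, nu1, n1))
  p2 <- list(lo = per_pop_at(br2$lo, nu2, n2),
             hi = if (br2$w > 1e-9) per_pop_at(br2$hi, nu2, n2))
  joint <- matrix(0, n1 + 1, n2 + 1)
  combos <- list(
    list(w = (1 - br1$w) * (1 - br2$w), k1 = br1$lo, a = p1$lo, k2 = br2$lo, b = p2$lo),
    list(w = br1$w * (1 - br2$w), k1 = br1$hi, a = p1$hi, k2 = br2$lo, b = p2$lo),
    list(w = (1 - br1$w) * br2$w, k1 = br1$lo, a = p1$lo, k2 = br2$hi, b = p2$hi),
    list(w = br1$w * br2$w, k1 = br1$hi, a = p1$hi, k2 = br2$hi, b = p2$hi)
  )
  for (cb in combos) {
    if (cb$w < 1e-12) next
    joint <- joint + cb$w *
      (t(cb$a$cond) %*% standing_joint(cb$k1, cb$k2) %*% cb$b$cond)
  }
  mut1 <- if (br1$w > 1e-9) {
    (1 - br1$w) * p1$lo$new_mut + br1$w * p1$hi$new_mut
  } else p1$lo$new_mut
  mut2 <- if (br2$w > 1e-9) {
    (1 - br2$w) * p2$lo$new_mut + br2$w * p2$hi$new_mut
  } else p2$lo$new_mut
  joint[, 1] <- joint[, 1] + mut1   # private to pop1: absent in pop2
  joint[1, ] <- joint[1, ] + mut2
  joint
}

sfs_mig <- function(K, nu1, nu2, T, n1, n2, m12, m21) {
  g_lo <- as.integer(floor(T * K))
  wg <- T * K - g_lo
  at_grids <- function(K1, K2) {
    w <- standing_joint(K1, K2)              # joint mass at the split
    a1 <- rep(0:K1, times = K2 + 1) / K1     # column-major state layout
    a2 <- rep(0:K2, each = K1 + 1) / K2
    inj <- matrix(0, K1 + 1, K2 + 1)
    inj[2, 1] <- nu1 / 2
    inj[1, 2] <- nu2 / 2
    p1 <- pmin(pmax((1 - m12) * a1 + m12 * a2, 0), 1)
    p2 <- pmin(pmax((1 - m21) * a2 + m21 * a1, 0), 1)
    tb1 <- matrix(dbinom(rep(0:K1, each = length(p1)), K1, p1),
                  length(p1), K1 + 1)
    tb2 <- matrix(dbinom(rep(0:K2, each = length(p2)), K2, p2),
                  length(p2), K2 + 1)
    step <- function(w) {
      ws <- as.vector(w + inj)
      matrix(crossprod(tb1 * ws, tb2), K1 + 1, K2 + 1)
    }
    for (t in seq_len(g_lo)) w <- step(w)
    smp1 <- outer(0:K1, 0:n1, function(a, j) dbinom(j, n1, a / K1))
    smp2 <- outer(0:K2, 0:n2, function(a, j) dbinom(j, n2, a / K2))
    out <- t(smp1) %*% w %*% smp2
    if (wg > 1e-9) {
      out_hi <- t(smp1) %*% step(w) %*% smp2
      out <- (1 - wg) * out + wg * out_hi
    }
    out
  }
  br1 <- grid_bracket(K, nu1)
  br2 <- grid_bracket(K, nu2)
  out <- (1 - br1$w) * (1 - br2$w) * at_grids(br1$lo, br2$lo)
  if (br1$w > 1e-9) out <- out + br1$w * (1 - br2$w) * at_grids(br1$hi, br2$lo)
  if (br2$w > 1e-9) out <- out + (1 - br1$w) * br2$w * at_grids(br1$lo, br2$hi)
  if (br1$w > 1e-9 && br2$w > 1e-9) {
    out <- out + br1$w * br2$w * at_grids(br1$hi, br2$hi)
  }
  out
}

#' Coalescent expected joint SFS (stochastic backend)
#'
#' Monte Carlo estimate of the expected joint SFS under the no-migration
#' split model, from the average branch lengths of simulated structured
#' genealogies. Serves as an independent cross-check of the Wright-Fisher
#' matrix backend: `E[sites in cell (i, j)] = E[T_ij] / 2` per unit theta,
#' with time in units of `2 N_ref` generations.
#'
#' @param params named list: `nu1`, `nu2`, `T` (as in
#'   [expected_joint_sfs()]).
#' @param n1,n2 haplotype sample sizes.
#' @param n_trees number of independent genealogies.
#' @param fold fold the spectrum.
#' @param seed optional integer seed.
#' @return a `joint_sfs` with the per-cell Monte Carlo standard error of
#'   the mean in attribute `se` (same folding applied).
#' @export
coalescent_expected_sfs <- function(params, n1, n2, n_trees = 2000,
                                    fold = TRUE, seed = NULL) {
  params <- as.list(params)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, n1 + 1, n2 + 1)
  acc2 <- matrix(0, n1 + 1, n2 + 1)
  for (k in seq_len(n_trees)) {
    segs <- sim_split_genealogy(n1, n2, params$nu1, params$nu2, params$T)
    tree <- matrix(0, n1 + 1, n2 + 1)
    for (s in seq_along(segs$len)) {
      d <- segs$desc[[s]]
      i <- sum(d <= n1)
      j <- length(d) - i
      tree[i + 1, j + 1] <- tree[i + 1, j + 1] + segs$len[s]
    }
    acc <- acc + tree
    acc2 <- acc2 + tree^2
  }
  mean_t <- acc / n_trees
  se_t <- sqrt(pmax(acc2 / n_trees - mean_t^2, 0) / n_trees)
  s <- new_joint_sfs(mean_t / 2, n1, n2, folded = FALSE)
  se <- new_joint_sfs(se_t / 2, n1, n2, folded = FALSE)
  if (fold) {
    s <- fold_sfs(s)
    # SEs of folded cells add in quadrature; folding sums independent cells
    se2 <- fold_sfs(new_joint_sfs((se_t / 2)^2, n1, n2, folded = FALSE))
    se <- se2
    se$counts <- sqrt(se2$counts)
  }
  attr(s, "se") <- se$counts
  s
}

# Poisson composite log-likelihood with theta profiled analytically
composite_loglik <- function(obs, model_sfs) {
  use <- !(obs$mask | model_sfs$mask)
  o <- obs$counts[use]
  m <- pmax(model_sfs$counts[use], 1e-300)
  theta <- sum(o) / sum(m)
  ll <- sum(o * log(theta * m) - theta * m)
  list(loglik = ll, theta = theta)
}

#' Fit a divergence model to an observed joint SFS
#'
#' Maximises the Poisson composite log-likelihood
#' `sum(obs * log(theta * M) - theta * M)` over unmasked cells, with the
#' scale `theta` profiled analytically (`theta_hat = sum(obs) / sum(M)`).
#' Optimisation uses COBYLA (derivative-free, honouring the
#' `nu1 + nu2 <= 1` constraint) on log10-transformed size and time
#' parameters, restarted from `n_restarts` random points within the bounds.
#' Restarts whose objective ends more than 10 log-likelihood units below
#' the best are flagged as probable local optima.
#'
#' @param obs observed `joint_sfs` (folded or unfolded; the model spectrum
#'   is folded to match).
#' @param model `"split_nomig"` (parameters `nu1`, `nu2`, `T`) or
#'   `"split_mig"` (additionally `m12`, `m21`).
#' @param n_restarts random restarts.
#' @param seed optional integer seed.
#' @param n_grid grid size passed to [expected_joint_sfs()].
#' @param bounds optional named list of `c(lower, upper)` overrides on the
#'   natural scale for `nu1`, `nu2`, `T`, `m12`, `m21`.
#' @param maxeval COBYLA evaluation cap per restart.
#' @param init optional list of named parameter vectors used as additional
#'   warm starts (e.g. the simple-model optimum when fitting the migration
#'   model, which also guarantees the nested fit is not out-optimised).
#' @return a `demographic_fit`: list with `model`, `par` (named vector),
#'   `theta_hat`, `loglik`, `restarts` (tibble with a `local_optimum`
#'   flag), `n_grid`, `convergence`.
#' @export
fit_model <- function(obs, model = c("split_nomig", "split_mig"),
                      n_restarts = 26, seed = NULL, n_grid = 100,
                      bounds = NULL, maxeval = 400, init = NULL) {
  model <- match.arg(model)
  if (sum(obs$counts[!obs$mask]) <= 0) {
    abort("observed SFS is empty over unmasked cells.")
  }
  if (!is.null(seed)) set.seed(seed)
  b <- list(nu1 = c(1e-3, 1), nu2 = c(1e-3, 1), T = c(1e-4, 5),
            m12 = c(0, 10), m21 = c(0, 10))
  for (nm in names(bounds)) b[[nm]] <- bounds[[nm]]
  par_names <- if (model == "split_nomig") c("nu1", "nu2", "T") else
    c("nu1", "nu2", "T", "m12", "m21")
  log_scaled <- par_names %in% c("nu1", "nu2", "T")
  lower <- vapply(par_names, function(p) b[[p]][1], numeric(1))
  upper <- vapply(par_names, function(p) b[[p]][2], numeric(1))
  to_opt <- function(x) ifelse(log_scaled, log10(x), x)
  from_opt <- function(x) ifelse(log_scaled, 10^x, x)
  obj <- function(xo) {
    p <- as.list(setNames(from_opt(xo), par_names))
    if (p$nu1 + p$nu2 > 1) return(1e12 * (p$nu1 + p$nu2))
    m <- expected_joint_sfs(model, p, obs$n1, obs$n2, n_grid = n_grid,
                            fold = obs$folded)
    -composite_loglik(obs, m)$loglik
  }
  hin <- function(xo) {
    p <- from_opt(xo)
    p[1] + p[2] - 1  # feasible when <= 0
  }
  lo <- to_opt(lower)
  hi <- to_opt(upper)
  starts <- lapply(init, function(p) {
    pmin(pmax(to_opt(unname(p[par_names])), lo), hi)
  })
  rows <- list()
  for (r in seq_len(n_restarts + length(starts))) {
    if (r <= length(starts)) {
      x0 <- starts[[r]]
    } else {
      repeat {
        x0 <- runif(length(par_names), lo, hi)
        p0 <- from_opt(x0)
        if (p0[1] + p0[2] <= 1) break
      }
    }
    fit <- tryCatch(
      nloptr::cobyla(x0, obj, lower = lo, upper = hi, hin = hin,
                     control = list(xtol_rel = 1e-7, maxeval = maxeval),
                     deprecatedBehavior = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      rows[[r]] <- tibble(restart = r, loglik = NA_real_, convergence = NA_integer_)
      next
    }
    pp <- from_opt(fit$par)
    rows[[r]] <- as_tibble(c(
      list(restart = r, loglik = -fit$value, convergence = fit$convergence),
      setNames(as.list(pp), par_names)
    ))
  }
  restarts <- bind_rows(rows)
  if (all(is.na(restarts$loglik))) {
    abort("all optimisation restarts failed; see the restart table.")
  }
  best_i <- which.max(restarts$loglik)
  restarts$local_optimum <- restarts$loglik < restarts$loglik[best_i] - 10
  best_par <- unlist(restarts[best_i, par_names])
  # polish: COBYLA's trust region shrinks as evaluations accrue; restarting
  # from the incumbent optimum tightens convergence, repeated while it helps
  best_ll <- restarts$loglik[best_i]
  for (k in 1:3) {
    polish <- tryCatch(
      nloptr::cobyla(pmin(pmax(to_opt(best_par), lo), hi), obj,
                     lower = lo, upper = hi, hin = hin,
                     control = list(xtol_rel = 1e-7, maxeval = maxeval),
                     deprecatedBehavior = FALSE),
      error = function(e) NULL
    )
    if (is.null(polish) || -polish$value < best_ll + 1e-6) break
    best_ll <- -polish$value
    best_par <- setNames(from_opt(polish$par), par_names)
  }
  m_best <- expected_joint_sfs(model, as.list(best_par), obs$n1, obs$n2,
                               n_grid = n_grid, fold = obs$folded)
  cl <- composite_loglik(obs, m_best)
  structure(
    list(
      model = model, par = best_par, theta_hat = cl$theta,
      loglik = cl$loglik, restarts = restarts, n_grid = n_grid,
      n1 = obs$n1, n2 = obs$n2, folded = obs$folded,
      convergence = restarts$convergence[best_i]
    ),
    class = "demographic_fit"
  )
}

#' @export
print.demographic_fit <- function(x, ...) {
  cat(sprintf("<demographic_fit> %s: %s; theta_hat = %.4g, loglik = %.3f (%d restarts)\n",
              x$model,
              paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
              x$theta_hat, x$loglik, nrow(x$restarts)))
  invisible(x)
}

#' Likelihood-ratio test between nested demographic fits
#'
#' `D = 2 (LL_complex - LL_simple)` against a chi-square with `df` degrees
#' of freedom. A clearly negative `D` cannot arise from nested models at
#' their optima and is flagged as an optimiser failure (a restart stuck in
#' a local optimum), mirroring the screening practice for replicated fits.
#'
#' @param fit_simple,fit_complex `demographic_fit` objects, simple nested in
#'   complex.
#' @param df degrees of freedom (default 2: the two migration rates).
#' @param alpha significance level.
#' @param tol numerical slack on the nesting inequality, absorbing optimiser
#'   and backend round-off; `D` within `[-tol, 0]` is treated as 0.
#' @return list with `statistic`, `p_value`, `complex_supported`,
#'   `optimizer_failure`.
#' @export
lrt <- function(fit_simple, fit_complex, df = 2, alpha = 0.05, tol = 0.05) {
  d <- 2 * (fit_complex$loglik - fit_simple$loglik)
  fail <- d < -tol
  d_stat <- max(d, 0)
  p <- pchisq(d_stat, df = df, lower.tail = FALSE)
  list(
    statistic = d_stat, p_value = p,
    complex_supported = !fail && p < alpha,
    optimizer_failure = fail
  )
}

#' Effective sequence length for real-time scaling
#'
#' The SNP matrix only covers sites that survived missing-data filtering,
#' so the invariant-site total is deflated by the SNP retention fraction:
#' `L = total_sites * snps_post / snps_pre`.
#'
#' @param total_sites sites (variant + invariant) in the unfiltered data.
#' @param snps_pre,snps_post SNP counts before and after filtering.
#' @return effective length in bp.
#' @export
effective_length <- function(total_sites, snps_pre, snps_post) {
  if (snps_pre <= 0) abort("`snps_pre` must be positive.")
  if (snps_post > snps_pre) abort("`snps_post` cannot exceed `snps_pre`.")
  if (total_sites <= 0 || snps_post < 0) abort("counts must be positive.")
  total_sites * snps_post / snps_pre
}

#' Scale a demographic fit to real time
#'
#' Converts the composite-likelihood scale and the relative divergence time
#' to demographic units: `N_ref = theta_hat / (4 mu L)` diploids,
#' `T_generations = T * 2 * N_ref`, `T_years = T_generations *
#' generation_time`. Computed for every supplied mutation rate; the default
#' set spans human (2.5e-8), cichlid (3.5e-9), Atlantic herring (2e-9) and
#' an average fish (5.97e-9) per-site per-generation rate, because no
#' sauger-specific estimate exists.
#'
#' @param fit a `demographic_fit`.
#' @param mu per-site per-generation mutation rate(s).
#' @param L effective sequence length in bp (see [effective_length()]).
#' @param generation_time years per generation (default 3, typical for
#'   sauger).
#' @return a tibble: `mu`, `n_ref`, `t_generations`, `t_years`, plus the
#'   absolute daughter sizes `n1_dip`, `n2_dip`.
#' @export
scale_to_real <- function(fit, mu = c(2.5e-8, 3.5e-9, 2e-9, 5.97e-9), L,
                          generation_time = 3) {
  if (any(mu <= 0) || L <= 0 || generation_time <= 0) {
    abort("`mu`, `L` and `generation_time` must be positive.")
  }
  n_ref <- fit$theta_hat / (4 * mu * L)
  t_gen <- unname(fit$par["T"]) * 2 * n_ref
  tibble(
    mu = mu, n_ref = n_ref,
    t_generations = t_gen, t_years = t_gen * generation_time,
    n1_dip = unname(fit$par["nu1"]) * n_ref,
    n2_dip = unname(fit$par["nu2"]) * n_ref
  )
}

#' Block bootstrap of the joint SFS
#'
#' Tiles the genome into contiguous blocks of `block_size` bp by coordinate,
#' resamples blocks with replacement, and tabulates one joint SFS per
#' replicate. Meant to feed percentile confidence intervals for refit
#' parameters while respecting linkage within blocks.
#'
#' @param gm a [gmat] (loci carry coordinates).
#' @param pops per-sample population labels (two populations).
#' @param block_size block length in bp (default 1 Mb).
#' @param B replicates (>= 1).
#' @param n1,n2,fold passed to [joint_sfs()].
#' @param seed optional integer seed.
#' @return list of `B` `joint_sfs` objects; block count in attribute
#'   `n_blocks`.
#' @export
block_bootstrap <- function(gm, pops, block_size = 1e6, B = 100,
                            n1 = NULL, n2 = NULL, fold = TRUE, seed = NULL) {
  if (B < 1) abort("`B` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  block <- paste0(gm$chrom, "_b", (gm$pos - 1) %/% block_size)
  blocks <- unique(block)
  if (length(blocks) == 1) {
    warn("block_bootstrap: a single block; replicates are degenerate copies.")
  }
  reps <- lapply(seq_len(B), function(b) {
    picked <- sample(blocks, length(blocks), replace = TRUE)
    idx <- unlist(lapply(picked, function(bl) which(block == bl)),
                  use.names = FALSE)
    # duplicated loci get jittered ids via subsetting with repeats not
    # supported by gmat (coordinates must be unique), so tabulate directly
    sub_counts <- function(rows) {
      cc <- allele_counts(gm, rows)
      cc[idx, , drop = FALSE]
    }
    pops_chr <- as.character(pops)
    lv <- sort(unique(pops_chr[!is.na(pops_chr)]))
    c1 <- sub_counts(!is.na(pops_chr) & pops_chr == lv[1])
    c2 <- sub_counts(!is.na(pops_chr) & pops_chr == lv[2])
    nn1 <- n1 %||% (2 * sum(pops_chr == lv[1], na.rm = TRUE))
    nn2 <- n2 %||% (2 * sum(pops_chr == lv[2], na.rm = TRUE))
    usable <- c1$n_chr >= nn1 & c2$n_chr >= nn2
    m <- matrix(0, nn1 + 1, nn2 + 1)
    for (l in which(usable)) {
      w1 <- dhyper(0:nn1, c1$alt[l], c1$n_chr[l] - c1$alt[l], nn1)
      w2 <- dhyper(0:nn2, c2$alt[l], c2$n_chr[l] - c2$alt[l], nn2)
      m <- m + outer(w1, w2)
    }
    s <- new_joint_sfs(m, nn1, nn2, folded = FALSE)
    if (fold) s <- fold_sfs(s)
    s
  })
  attr(reps, "n_blocks") <- length(blocks)
  reps
}

#' Percentile confidence intervals from bootstrap refits
#'
#' Refits a model to each bootstrap spectrum (few restarts each; the
#' point-estimate parameters make a good warm start) and returns percentile
#' intervals for every parameter.
#'
#' @param sfs_list list of `joint_sfs` replicates (see [block_bootstrap()]).
#' @param model,n_grid as in [fit_model()].
#' @param n_restarts restarts per replicate fit.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return list with `ci` (tibble: `param`, `lower`, `upper`) and `fits`
#'   (tibble of per-replicate parameter estimates).
#' @export
bootstrap_fit_ci <- function(sfs_list, model = "split_nomig", n_grid = 100,
                             n_restarts = 3, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- map_dfr(seq_along(sfs_list), function(i) {
    f <- fit_model(sfs_list[[i]], model, n_restarts = n_restarts,
                   n_grid = n_grid)
    as_tibble(c(list(replicate = i, loglik = f$loglik,
                     theta_hat = f$theta_hat), as.list(f$par)))
  })
  a <- (1 - level) / 2
  pars <- setdiff(names(fits), c("replicate", "loglik"))
  ci <- map_dfr(pars, function(p) {
    tibble(param = p,
           lower = quantile(fits[[p]], a, names = FALSE),
           upper = quantile(fits[[p]], 1 - a, names = FALSE))
  })
  list(ci = ci, fits = fits)
}

#' Sample an observed SFS from an expected spectrum
#'
#' Draws a multinomial sample of `n_sites` segregating sites over the
#' unmasked cells of an expected spectrum (each independent site falls in a
#' cell with probability proportional to its expected mass). This is the
#' generative counterpart of the Poisson composite likelihood for
#' independent sites and is used for parametric simulation, e.g. type-I
#' calibration of the likelihood-ratio test.
#'
#' @param sfs a `joint_sfs` of expected counts.
#' @param n_sites number of sites to draw.
#' @param seed optional integer seed.
#' @return a `joint_sfs` of integer counts with the same mask/folding.
#' @export
sample_sfs <- function(sfs, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  use <- !sfs$mask & sfs$counts > 0
  pr <- sfs$counts[use] / sum(sfs$counts[use])
  draw <- as.vector(rmultinom(1, n_sites, pr))
  out <- sfs
  out$counts[] <- 0
  out$counts[use] <- draw
  out
}

#' Write / read a joint SFS as flat text
#'
#' A dadi-compatible layout: a header line with the grid dimensions
#' (`n1 + 1`, `n2 + 1`) and the folding flag, one line of row-major
#' entries, and one line of row-major mask indicators (1 = masked).
#'
#' @param sfs a `joint_sfs`.
#' @param path file path.
#' @return `path` (write) or a `joint_sfs` (read).
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %s", sfs$n1 + 1, sfs$n2 + 1,
                     if (sfs$folded) "folded" else "unfolded"), con)
  writeLines(paste(signif(as.vector(t(sfs$counts)), 12), collapse = " "), con)
  writeLines(paste(as.integer(as.vector(t(sfs$mask))), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  vals <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  msk <- as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]]) == 1L
  counts <- matrix(vals, d1, d2, byrow = TRUE)
  mask <- matrix(msk, d1, d2, byrow = TRUE)
  new_joint_sfs(counts, d1 - 1L, d2 - 1L, folded = folded, mask = mask)
}
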