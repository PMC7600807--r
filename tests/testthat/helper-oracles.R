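# Independent brute-force oracles and small fixture builders.  Everything
# here is deliberately naive (threshold sweeps, BFS components, normal
# equations) and shares no code with the package internals it checks.

# --- fixtures ---------------------------------------------------------------

make_manifest <- function(n_control, n_patient, seed = 1) {
  set.seed(seed)
  n <- n_control + n_patient
  as_cohort_manifest(data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", "patient"), c(n_control, n_patient)),
    age_years = round(runif(n, 3.4, 17.0), 2),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

make_ball_mask <- function(grid, radius) {
  ctr <- (grid + 1) / 2
  idx <- arrayInd(seq_len(prod(grid)), grid)
  array(rowSums(sweep(idx, 2, ctr)^2) <= radius^2, dim = grid)
}

make_stack <- function(n_control, n_patient, grid = c(4L, 4L, 3L),
                       seed = 1, mask = NULL) {
  man <- make_manifest(n_control, n_patient, seed = seed)
  if (is.null(mask)) mask <- array(TRUE, grid)
  set.seed(seed + 1000)
  vols <- lapply(seq_len(nrow(man)),
                 function(i) array(rnorm(prod(grid)), grid))
  masked_stack(vols, mask, man)
}

# --- TFCE oracle: plain threshold sweep with BFS components -----------------

bfs_components <- function(supra, coords, dims, connectivity) {
  n <- nrow(coords)
  key <- coords[, 1] + dims[1] * (coords[, 2] + dims[2] * coords[, 3])
  lookup <- new.env(hash = TRUE)
  for (v in which(supra)) assign(as.character(key[v]), v, envir = lookup)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ,
               drop = FALSE]
  comp <- integer(n)
  cur <- 0L
  for (start in which(supra)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- coords[v, ] + offs[k, ]
        if (any(nb < 0) || any(nb >= dims)) next
        hit <- mget(as.character(nb[1] + dims[1] * (nb[2] + dims[2] * nb[3])),
                    envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && comp[hit] == 0L) {
          comp[hit] <- cur
          queue <- c(queue, hit)
        }
      }
    }
  }
  comp
}

tfce_oracle <- function(stat, coords, dims, E = 0.5, H = 2, n_steps = 100,
                        connectivity = 26) {
  n <- length(stat)
  out <- numeric(n)
  hmax <- max(stat)
  if (hmax <= 0) return(out)
  dh <- hmax / n_steps
  for (step in seq_len(n_steps)) {
    h <- hmax * step / n_steps
    supra <- stat >= h
    if (!any(supra)) next
    comp <- bfs_components(supra, coords, dims, connectivity)
    sizes <- tabulate(comp)
    out[supra] <- out[supra] + sizes[comp[supra]]^E * h^H * dh
  }
  out
}

# --- exhaustive permutation oracle ------------------------------------------

# All distinct relabelings preserving group sizes; returns the per-voxel
# p-values of the TFCE-enhanced absolute mean-difference statistic.
perm_oracle_exhaustive <- function(data, labels, coords, dims,
                                   E = 0.5, H = 2, n_steps = 100,
                                   connectivity = 26) {
  n <- nrow(data)
  n_pat <- sum(labels == "patient")
  combos <- utils::combn(n, n_pat)
  enhanced <- matrix(NA_real_, ncol(combos), ncol(data))
  for (j in seq_len(ncol(combos))) {
    pat <- seq_len(n) %in% combos[, j]
    d <- abs(colMeans(data[pat, , drop = FALSE]) -
             colMeans(data[!pat, , drop = FALSE]))
    enhanced[j, ] <- tfce_oracle(d, coords, dims, E, H, n_steps, connectivity)
  }
  pat_obs <- labels == "patient"
  d_obs <- abs(colMeans(data[pat_obs, , drop = FALSE]) -
               colMeans(data[!pat_obs, , drop = FALSE]))
  t_obs <- tfce_oracle(d_obs, coords, dims, E, H, n_steps, connectivity)
  p <- vapply(seq_along(t_obs),
              function(v) mean(enhanced[, v] >= t_obs[v]), numeric(1))
  list(p = p, t_obs = t_obs, n_labelings = ncol(combos))
}

# --- least squares / Welch formula oracles ----------------------------------

ls_oracle <- function(X, Y) {
  XtX <- crossprod(X)
  B <- solve(XtX, crossprod(X, Y))
  list(coef = B, resid = Y - X %*% B,
       cov_unscaled = solve(XtX))
}

welch_oracle <- function(pat, ctl) {
  m1 <- mean(pat); m2 <- mean(ctl)
  v1 <- var(pat); v2 <- var(ctl)
  n1 <- length(pat); n2 <- length(ctl)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Sample of size n with exactly the requested mean and variance (n-1 denom).
sample_with_moments <- function(n, mean, variance, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  mean + x * sqrt(variance)
}
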