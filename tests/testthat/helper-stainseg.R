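# Shared fixtures and independent oracle implementations. Oracles are
# deliberately written as plain scalar loops, independent of the package's
# vectorized/taped code paths.

tiny_spec <- function(...) {
  nuclei_scene_spec(image_size = 64L, n_nuclei = 4L, radius_range = c(6, 11),
                    eccentricity_range = c(0, 0.5), overlap_allowed = FALSE,
                    ...)
}

random_image <- function(S, seed = 1) {
  r <- stainseg::rng_stream(seed)
  array(stainseg:::rng_runif(r, S * S * 3), c(S, S, 3))
}

# --- independent scalar-loop oracles -------------------------------------

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

oracle_ntxent_pair <- function(i, j, P, tau) {
  n <- nrow(P)
  den <- 0
  for (k in seq_len(n)) {
    if (k != i) den <- den + exp(oracle_cosine(P[i, ], P[k, ]) / tau)
  }
  -log(exp(oracle_cosine(P[i, ], P[j, ]) / tau) / den)
}

oracle_ntxent_batch <- function(P, tau) {
  n <- nrow(P)
  total <- 0
  for (k in seq_len(n / 2)) {
    total <- total + oracle_ntxent_pair(2 * k - 1, 2 * k, P, tau) +
      oracle_ntxent_pair(2 * k, 2 * k - 1, P, tau)
  }
  total / n
}

oracle_bce <- function(y, t, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    ti <- min(max(t[i], eps), 1 - eps)
    s <- s + -(y[i] * log(ti) + (1 - y[i]) * log(1 - ti))
  }
  s / length(y)
}

oracle_dice_loss <- function(y, t, smooth = 1e-6) {
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] * t[i]; d1 <- d1 + y[i]^2; d2 <- d2 + t[i]^2
  }
  1 - (2 * num + smooth) / (d1 + d2 + smooth)
}

oracle_confusion <- function(gt, pred) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(gt)) {
    g <- gt[i] > 0; p <- pred[i] > 0
    if (g && p) tp <- tp + 1L
    else if (!g && p) fp <- fp + 1L
    else if (g && !p) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Greedy best-match AJI with usage bookkeeping, all pairwise quantities
# computed by explicit pixel loops.
oracle_aji <- function(gt, pred) {
  gls <- sort(unique(gt[gt > 0]))
  pls <- sort(unique(pred[pred > 0]))
  if (length(gls) == 0 && length(pls) == 0) return(1)
  pix_set <- function(m, l) which(as.vector(m) == l)
  used <- rep(FALSE, length(pls))
  num <- 0; den <- 0
  for (gl in gls) {
    gset <- pix_set(gt, gl)
    best_j <- -1; best_jac <- -1; best_inter <- 0; best_union <- 0
    for (pi in seq_along(pls)) {
      if (used[pi]) next
      pset <- pix_set(pred, pls[pi])
      inter <- length(intersect(gset, pset))
      if (inter == 0) next
      un <- length(union(gset, pset))
      jac <- inter / un
      if (jac > best_jac) {
        best_jac <- jac; best_j <- pi; best_inter <- inter; best_union <- un
      }
    }
    if (best_j < 0) {
      den <- den + length(gset)
    } else {
      num <- num + best_inter
      den <- den + best_union
      used[best_j] <- TRUE
    }
  }
  for (pi in seq_along(pls)) {
    if (!used[pi]) den <- den + length(pix_set(pred, pls[pi]))
  }
  num / den
}

random_instance_mask <- function(S, max_inst, rng) {
  m <- matrix(0L, S, S)
  k <- stainseg:::rng_int(rng, 1, 0, max_inst)
  for (i in seq_len(k)) {
    r0 <- stainseg:::rng_int(rng, 1, 1, S - 1)
    c0 <- stainseg:::rng_int(rng, 1, 1, S - 1)
    h <- stainseg:::rng_int(rng, 1, 1, S - r0 + 1)
    w <- stainseg:::rng_int(rng, 1, 1, S - c0 + 1)
    m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- i
  }
  m
}

# Central finite-difference gradient check of a scalar-valued tape program.
# `fwd(g, leaves)` must rebuild the graph from the named parameter list.
fd_gradcheck <- function(fwd, params, n_probe = 4, eps = 1e-5, tol = 1e-4,
                         seed = 1) {
  g <- stainseg:::ad_graph()
  leaves <- lapply(names(params), function(nm) stainseg:::ad_leaf(g, params[[nm]], nm))
  names(leaves) <- names(params)
  loss <- fwd(g, leaves)
  stainseg:::ad_backward(g, loss)
  probe_rng <- stainseg::rng_stream(seed)
  worst <- 0
  for (nm in names(params)) {
    analytic <- g$leaves[[nm]]$grad
    idx <- unique(stainseg:::rng_int(probe_rng, n_probe, 1, length(params[[nm]])))
    for (i in idx) {
      ev <- function(pp) {
        gg <- stainseg:::ad_graph()
        ll <- lapply(names(pp), function(n) stainseg:::ad_leaf(gg, pp[[n]], n))
        names(ll) <- names(pp)
        fwd(gg, ll)$value
      }
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fdg <- (ev(up) - ev(dn)) / (2 * eps)
      rel <- abs(fdg - analytic[i]) / max(1e-6, abs(fdg) + abs(analytic[i]))
      worst <- max(worst, rel)
    }
  }
  worst
}
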