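# Independent brute-force oracles used across tests. These deliberately use
# different algorithms from the package implementations.

# winding-number point-in-polygon (package uses even-odd scanline)
bf_point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  wn <- 0
  on_edge <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    # on-edge check
    dr <- vr[j] - vr[i]; dc <- vc[j] - vc[i]
    len2 <- dr^2 + dc^2
    if (len2 > 0) {
      t_ <- ((pr - vr[i]) * dr + (pc - vc[i]) * dc) / len2
      if (t_ >= 0 && t_ <= 1) {
        d2 <- (pr - (vr[i] + t_ * dr))^2 + (pc - (vc[i] + t_ * dc))^2
        if (d2 < 1e-18) on_edge <- TRUE
      }
    }
    if (vr[i] <= pr) {
      if (vr[j] > pr && (dc * (pr - vr[i]) - dr * (pc - vc[i])) > 0) wn <- wn + 1
    } else {
      if (vr[j] <= pr && (dc * (pr - vr[i]) - dr * (pc - vc[i])) < 0) wn <- wn - 1
    }
  }
  if (on_edge) return(FALSE) # strictly inside
  wn != 0
}

bf_rasterize <- function(vr, vc, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  for (r in 0:(nrow - 1)) for (c in 0:(ncol - 1)) {
    out[r + 1, c + 1] <- bf_point_in_polygon(r, c, vr, vc)
  }
  out
}

# queue-based BFS flood fill from the border over background (package uses
# iterative pmax label propagation)
bf_fill_holes_slice <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  bg <- !sl
  seen <- matrix(FALSE, nr, nc)
  queue <- list()
  for (r in 1:nr) for (c in c(1, nc)) if (bg[r, c]) queue[[length(queue) + 1]] <- c(r, c)
  for (c in 1:nc) for (r in c(1, nr)) if (bg[r, c]) queue[[length(queue) + 1]] <- c(r, c)
  while (length(queue) > 0) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    if (seen[p[1], p[2]]) next
    seen[p[1], p[2]] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          bg[q[1], q[2]] && !seen[q[1], q[2]]) {
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  sl | (bg & !seen)
}

# pairwise enumeration AUROC
bf_auroc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# explicit-loop overlap counting
bf_overlap_counts <- function(x, y) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  xv <- as.vector(x); yv <- as.vector(y)
  for (i in seq_along(xv)) {
    if (xv[i] == 1 && yv[i] == 1) tp <- tp + 1
    else if (xv[i] == 1) fp <- fp + 1
    else if (yv[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# small, fast phantom spec used in many tests; named args override defaults
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48L, 48L, 24L), bone_radius_mm = 1.2,
         shell_thickness_mm = 0.3, axis_curvature_mm = 0.2,
         noise_sigma = 0, n_distractors = 0L, annotated_range = c(0L, 20L)),
    list(...)
  )
  do.call(phantom_spec, args)
}

# preprocessed desk-scale cohort for training tests
make_training_cohort <- function(n, seed, noise_sigma = 0,
                                 target = c(64L, 64L, 16L)) {
  base <- phantom_spec(
    grid_shape = c(64L, 64L, 40L), bone_radius_mm = 1.6,
    shell_thickness_mm = 0.35, axis_curvature_mm = 0.25,
    noise_sigma = noise_sigma, n_distractors = 1L,
    annotated_range = c(0L, 32L)
  )
  coh <- generate_cohort(
    n, base,
    variation = list(bone_radius_mm = c(1.3, 1.8),
                     trabecular_density = c(150, 260)),
    seed = seed
  )
  prep <- lapply(coh$cases, function(cs) {
    pc <- preprocess_case(cs$volume, cs$annotation, target)
    list(id = cs$volume$case_id, x = pc$x$intensities, y = pc$y$values,
         record = pc$record)
  })
  list(cohort = coh, prep = prep)
}
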