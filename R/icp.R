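# Rigid-similarity registration (ICP) ---------------------------------------

#' Rigid similarity transform
#' @param rotation 3x3 orthonormal, det +1
#' @param translation length-3 vector (mm)
#' @param scale positive scalar
#' @return `rigid_similarity`
#' @export
rigid_similarity <- function(rotation = diag(3), translation = c(0, 0, 0),
                             scale = 1) {
  stopifnot(abs(det(rotation) - 1) < 1e-8, scale > 0)
  structure(list(R = rotation, t = as.numeric(translation), s = scale),
            class = "rigid_similarity")
}

#' Apply a similarity transform to points
#' @param tf `rigid_similarity`
#' @param pts n x 3 matrix
#' @return transformed points
#' @export
apply_similarity <- function(tf, pts) {
  sweep(tf$s * (as.matrix(pts) %*% t(tf$R)), 2, -tf$t)
}

#' Compose two similarities (apply `a` after `b`)
#' @param a,b transforms
#' @return combined transform
#' @export
compose_similarity <- function(a, b) {
  rigid_similarity(a$R %*% b$R, a$s * (a$R %*% b$t) + a$t, a$s * b$s)
}

# closed-form least-squares similarity (Umeyama) from matched pairs
umeyama <- function(src, dst, with_scale = TRUE) {
  ms <- colMeans(src); md <- colMeans(dst)
  S <- sweep(src, 2, ms); D <- sweep(dst, 2, md)
  H <- crossprod(S, D) / nrow(src)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Sg <- diag(c(1, 1, d))
  R <- sv$v %*% Sg %*% t(sv$u)
  s <- if (with_scale) max(sum(sv$d * c(1, 1, d)) / mean(rowSums(S^2)),
                           1e-8) else 1
  t_ <- md - s * as.vector(R %*% ms)
  rigid_similarity(R, t_, s)
}

# brute-force nearest neighbours (target sets are small rings/clouds)
nearest_idx <- function(src, tgt) {
  n <- nrow(src)
  out <- integer(n)
  step <- max(1, floor(2e6 / nrow(tgt)))
  for (s0 in seq(1, n, by = step)) {
    s1 <- min(n, s0 + step - 1)
    d2 <- outer(rowSums(src[s0:s1, , drop = FALSE]^2), rowSums(tgt^2), "+") -
      2 * src[s0:s1, , drop = FALSE] %*% t(tgt)
    out[s0:s1] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Iterative closest point with similarity updates
#'
#' Point-to-point ICP; each iteration matches every source point to its
#' nearest target point and applies the closed-form optimal similarity, so
#' the mean closest-point distance is non-increasing. Terminates on relative
#' improvement below `tol` or `max_iter`. Exact registration of identically
#' sampled clouds requires the initial misalignment to sit below the point
#' spacing (a PCA coarse fit provides this in the mounting pipeline);
#' otherwise the algorithm settles on the usual nearest-neighbour plateau.
#'
#' @param source,target point clouds (n x 3, mm)
#' @param init initial [rigid_similarity()] (e.g. a PCA coarse fit)
#' @param with_scale allow a scale factor
#' @param max_iter,tol iteration controls
#' @return list(transform, rms, iters, converged, warning_flag)
#' @export
icp_align <- function(source, target, init = rigid_similarity(),
                      with_scale = TRUE, max_iter = 100, tol = 1e-8) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    abort_sf("ICP needs at least 3 points per cloud", "sacflow_parameter_error")
  tf <- init
  cur <- apply_similarity(tf, source)
  best <- NULL; best_rms <- Inf
  rms_prev <- Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    nn <- nearest_idx(cur, target)
    matched <- target[nn, , drop = FALSE]
    rms <- sqrt(mean(rowSums((cur - matched)^2)))
    if (rms < best_rms) { best_rms <- rms; best <- tf }
    if (rms < 1e-12 ||
        (is.finite(rms_prev) && abs(rms_prev - rms) <= tol * max(rms_prev, 1e-300))) {
      converged <- TRUE; break
    }
    rms_prev <- rms
    upd <- umeyama(cur, matched, with_scale)
    tf <- compose_similarity(upd, tf)
    cur <- apply_similarity(tf, source)
  }
  if (!converged) tf <- best
  list(transform = tf, rms = best_rms, iters = it, converged = converged,
       warning_flag = !converged)
}
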