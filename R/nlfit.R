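#' Nonlinear complex fitting of the total field over echoes
#'
#' Per voxel, minimises `sum_i |S_i - M_i exp(i(phi0 + gamma dB TE_i))|^2`
#' over the total-field perturbation `dB` and the TE-independent phase
#' offset `phi0`, where `S_i` is the measured complex signal and `M_i` its
#' measured magnitude. Modelling the Gaussian noise on the real and
#' imaginary channels (rather than on the phase) makes this the
#' statistically matched multi-echo combination; it is the only combination
#' rule here that also estimates `phi0`.
#'
#' The solver is Gauss-Newton on the two phase parameters, vectorised over
#' voxels: the magnitude-weighted 2x2 normal equations are solved in closed
#' form at every iteration. It is initialised from a magnitude-squared
#' weighted least-squares line through the temporally unwrapped phase.
#'
#' @param gre A [multi_echo_gre()] (needs >= 3 echoes for a stable
#'   slope/offset fit; 2 echoes give the exact two-point line).
#' @param mask Optional 3D logical array: only these voxels are fitted
#'   (air voxels converge slowly and never enter the masked pipelines, so
#'   restricting the fit is both faster and cleaner). Outside the mask the
#'   outputs are 0 and the residual is `NaN`.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Stop when the largest relative parameter update falls below
#'   this value.
#' @return List: `db_total` ([field_map()] in Tesla), `phi0` (3D radians),
#'   `residual` (3D final residual norm; `NaN` flags voxels with zero
#'   magnitude at every echo, where both outputs are set to 0).
#' @export
nlfit_complex <- function(gre, mask = NULL, max_iter = 30, tol = 1e-6) {
  stopifnot(inherits(gre, "multi_echo_gre"))
  tes <- gre$echo_times_s
  ne <- length(tes)
  if (ne < 2) stop("at least 2 echoes required")
  shape <- dim(gre$magnitude)[1:3]
  mask <- as_mask(mask, shape)
  sel <- as.vector(mask)
  nvox <- sum(sel)
  M <- matrix(gre$magnitude, ncol = ne)[sel, , drop = FALSE]
  S <- matrix(complex(real = gre$magnitude * cos(gre$phase),
                      imaginary = gre$magnitude * sin(gre$phase)),
              ncol = ne)[sel, , drop = FALSE]
  bad <- rowSums(M) == 0
  gam <- gyromagnetic_ratio()

  # Initialisation: M^2-weighted LS line through the temporally unwrapped
  # phase, slope in rad/s and intercept in radians.
  pu <- matrix(temporal_unwrap(gre$phase, tes), ncol = ne)[sel, , drop = FALSE]
  w <- M^2
  sw <- rowSums(w)
  sw[sw == 0] <- 1
  swt <- as.vector(w %*% tes)
  swt2 <- as.vector(w %*% tes^2)
  swp <- rowSums(w * pu)
  swtp <- rowSums(w * pu * rep(tes, each = nvox))
  det0 <- sw * swt2 - swt^2
  det0[abs(det0) < 1e-300] <- 1
  b <- (sw * swtp - swt * swp) / det0    # rad/s
  p0 <- (swt2 * swp - swt * swtp) / det0 # rad

  for (it in seq_len(max_iter)) {
    theta <- outer(p0, rep(1, ne)) + outer(b, tes)
    f <- M * complex(real = cos(theta), imaginary = sin(theta))
    g <- Im(Conj(f) * S) # per-echo phase-misfit moment, |f|^2-weighted
    A <- rowSums(M^2)
    B <- as.vector((M^2) %*% tes)
    C <- as.vector((M^2) %*% tes^2)
    u <- rowSums(g)
    v <- as.vector(g %*% tes)
    det <- A * C - B^2
    det[abs(det) < 1e-300] <- 1
    dp0 <- (C * u - B * v) / det
    db <- (A * v - B * u) / det
    p0 <- p0 + dp0
    b <- b + db
    rel <- pmax(abs(db) / pmax(abs(b), 1e-12), abs(dp0) / pmax(abs(p0), 1e-12))
    rel[bad] <- 0
    if (max(rel) < tol) break
  }
  theta <- outer(p0, rep(1, ne)) + outer(b, tes)
  f <- M * complex(real = cos(theta), imaginary = sin(theta))
  res <- sqrt(rowSums(Mod(S - f)^2))
  b[bad] <- 0
  p0[bad] <- 0
  res[bad] <- NaN
  db_full <- array(0, dim = shape)
  p0_full <- array(0, dim = shape)
  res_full <- array(NaN, dim = shape)
  db_full[mask] <- b / gam
  p0_full[mask] <- p0
  res_full[mask] <- res
  list(db_total = field_map(db_full, "tesla", "total", mask),
       phi0 = p0_full, residual = res_full)
}
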