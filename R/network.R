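#' Poiseuille resistance of a vessel segment with varying radius
#'
#' `R = integral of 8 mu / (pi r_eff(s)^4) ds` evaluated with the
#' composite trapezoid rule on the arc grid. Geometry enters in mm and is
#' converted to SI, so the result is in Pa s/m^3.
#'
#' @param s arc-length grid (mm), increasing.
#' @param r_eff effective radius per grid point (mm), positive.
#' @param fluid a `fluid_properties`.
#' @return resistance (Pa s/m^3).
#' @export
segment_resistance <- function(s, r_eff, fluid = fluid_properties()) {
  if (any(r_eff <= 0)) stop("r_eff must be positive everywhere")
  if (length(s) != length(r_eff)) stop("grid mismatch")
  pracma::trapz(s * 1e-3, 8 * fluid$mu / (pi * (r_eff * 1e-3)^4))
}

# cumulative resistance along the grid (Pa s/m^3 at each s)
cumulative_resistance <- function(s, r_eff, fluid) {
  as.numeric(pracma::cumtrapz(s * 1e-3,
                              8 * fluid$mu / (pi * (r_eff * 1e-3)^4)))
}

#' Irreversible pressure loss of a stenosis (expansion loss)
#'
#' Post-stenotic expansion loss
#' `dP = Kt * (rho/2) * (Q/A_min - Q/A_ref)^2`, the standard augmentation
#' of the viscous (Poiseuille) drop for focal narrowings; it vanishes for
#' `A_min = A_ref` and grows quadratically in flow. The default loss
#' coefficient Kt = 1.52 is the classical sudden-expansion value.
#'
#' @param A_min minimal lumen area (mm^2).
#' @param A_ref reference (normal) lumen area (mm^2), `>= A_min`.
#' @param Q flow (mm^3/s).
#' @param fluid a `fluid_properties`.
#' @param Kt loss coefficient.
#' @return pressure loss (Pa), non-negative.
#' @export
stenosis_extra_loss <- function(A_min, A_ref, Q, fluid = fluid_properties(),
                                Kt = 1.52) {
  if (A_min <= 0 || A_min > A_ref) stop("require 0 < A_min <= A_ref")
  q_si <- Q * 1e-9
  am <- A_min * 1e-6
  ar <- A_ref * 1e-6
  Kt * (fluid$rho / 2) * (q_si / am - q_si / ar)^2
}

#' Resistive outlet model
#' @param R outlet resistance (Pa s/m^3).
#' @param P_distal back pressure (Pa).
#' @return list of class `outlet_resistance`.
#' @export
outlet_resistance <- function(R, P_distal = 0) {
  if (R <= 0) stop("R must be positive")
  structure(list(R = R, P_distal = P_distal), class = "outlet_resistance")
}

#' Vessel network for the reduced-order pressure solve
#'
#' A tree of branches, each carrying an arc grid and effective radius
#' profile (typically `s_mm` and `r_eff` of a [fuse()] result), an
#' optional lumped stenosis, and an outlet model at every leaf.
#'
#' @param branches list; each element a list with `id` (character),
#'   `parent` (character or NA for the root), `s` (mm, increasing),
#'   `r` (mm), and optional `stenosis = list(A_min, A_ref, s_pos, Kt)`
#'   (areas mm^2, position mm).
#' @param outlets named list keyed by leaf branch id; elements are
#'   [outlet_resistance()], [windkessel3()] or `windkessel2` objects
#'   (two-element models are treated quasi-statically as their resistance
#'   with zero back pressure).
#' @return object of class `vessel_network`.
#' @export
vessel_network <- function(branches, outlets) {
  ids <- vapply(branches, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate branch ids")
  parents <- vapply(branches, function(b)
    if (is.null(b$parent) || is.na(b$parent)) NA_character_ else b$parent,
    character(1))
  root <- ids[is.na(parents)]
  if (length(root) != 1) stop("exactly one root branch is required")
  if (any(!is.na(parents) & !(parents %in% ids)))
    stop("parent id not found in branch list")
  children <- lapply(ids, function(i) ids[which(parents == i)])
  names(children) <- ids
  # acyclicity / connectedness: every branch must reach the root
  for (i in seq_along(ids)) {
    cur <- ids[i]; seen <- character(0)
    while (!is.na(parents[match(cur, ids)])) {
      if (cur %in% seen) stop("cycle detected in branch topology")
      seen <- c(seen, cur)
      cur <- parents[match(cur, ids)]
    }
  }
  leaves <- ids[vapply(children, length, 1L) == 0]
  missing <- setdiff(leaves, names(outlets))
  if (length(missing) > 0)
    stop("leaf branch(es) without outlet model: ",
         paste(missing, collapse = ", "))
  names(branches) <- ids
  structure(list(branches = branches, outlets = outlets, root = root,
                 children = children, leaves = leaves),
            class = "vessel_network")
}

#' Build a single-branch network from a fused geometry
#'
#' Uses the effective radius profile of the fused geometry as the branch,
#' detects the minimal-area position, and attaches an expansion-loss
#' stenosis element there when the narrowing exceeds 2 percent of the
#' reference area.
#'
#' @param fused a `fused_geometry`.
#' @param outlet outlet model for the single leaf.
#' @param Kt stenosis loss coefficient.
#' @return a `vessel_network` with one branch `"main"`.
#' @export
network_from_fused <- function(fused, outlet, Kt = 1.52) {
  s <- fused$s_mm
  r <- fused$r_eff
  A <- pi * r^2
  i_min <- which.min(A)
  A_ref <- max(A)
  sten <- NULL
  if (A[i_min] < 0.98 * A_ref)
    sten <- list(A_min = A[i_min], A_ref = A_ref, s_pos = s[i_min], Kt = Kt)
  vessel_network(list(list(id = "main", parent = NA, s = s, r = r,
                           stenosis = sten)),
                 outlets = list(main = outlet))
}

# affine outlet relation P(Q) = a + b*Q at an instant
outlet_affine <- function(o, state) {
  if (inherits(o, "outlet_resistance")) c(o$P_distal, o$R)
  else if (inherits(o, "windkessel3")) c(state, o$Rp)
  else if (inherits(o, "windkessel2")) c(0, o$R)
  else stop("unsupported outlet model")
}

# one quasi-static solve at a single instant; r_extra holds the current
# linearization of each branch's stenosis loss as a resistance
solve_instant <- function(net, q_in, r_lin, r_extra, out_aff) {
  ids <- names(net$branches)
  a <- b <- stats::setNames(numeric(length(ids)), ids)
  order_up <- rev(network_order(net))
  for (id in order_up) {
    ch <- net$children[[id]]
    if (length(ch) == 0) {
      aff <- out_aff[[id]]
      a[id] <- aff[1]; b[id] <- aff[2]
    } else {
      invb <- sum(1 / b[ch])
      B <- 1 / invb
      a[id] <- B * sum(a[ch] / b[ch])
      b[id] <- B
    }
    b[id] <- b[id] + r_lin[id] + r_extra[id]
  }
  # top-down flow/pressure distribution
  Q <- stats::setNames(numeric(length(ids)), ids)
  P_up <- stats::setNames(numeric(length(ids)), ids)
  Q[net$root] <- q_in
  P_up[net$root] <- a[net$root] + b[net$root] * q_in
  for (id in network_order(net)) {
    p_node <- P_up[id] - (r_lin[id] + r_extra[id]) * Q[id]
    for (ch in net$children[[id]]) {
      Q[ch] <- (p_node - a[ch]) / b[ch]
      P_up[ch] <- p_node
    }
  }
  list(Q = Q, P_up = P_up)
}

# root-first traversal order
network_order <- function(net) {
  out <- net$root
  queue <- net$children[[net$root]]
  while (length(queue) > 0) {
    id <- queue[1]; queue <- queue[-1]
    out <- c(out, id)
    queue <- c(queue, net$children[[id]])
  }
  out
}

#' Quasi-static distributed-resistance pressure solve over a network
#'
#' Desk-scale surrogate for a full 3D transient CFD run: at each instant
#' the branch flows satisfy junction conservation and the outlet
#' pressure-flow relations, with each branch contributing its integrated
#' Poiseuille resistance plus (if present) the nonlinear stenosis
#' expansion loss, linearized and resolved by damped fixed-point
#' iteration to residual < 1e-8. Flow inertia is neglected (quasi-static
#' approximation): FFR uses time-averaged pressures, which at rest are
#' dominated by resistive losses. Stateful (three-element Windkessel)
#' outlets are advanced cycle by cycle until the pressure field is
#' periodic to 0.1 percent.
#'
#' @param net a `vessel_network`.
#' @param Q_in function of time returning inlet flow (m^3/s), T-periodic.
#' @param T cardiac period (s).
#' @param n_t time samples per cycle.
#' @param fluid a `fluid_properties`.
#' @param cycles maximum cycles for periodic convergence.
#' @param max_iter fixed-point iterations per instant.
#' @return object of class `pressure_solution`: `t`, `P_inlet` (Pa over
#'   the cycle), per-branch `s` (mm), `P` (n_s x n_t, Pa) and `Q`
#'   (m^3/s per instant).
#' @export
solve_network <- function(net, Q_in, T = 1, n_t = 101,
                          fluid = fluid_properties(), cycles = 20,
                          max_iter = 200) {
  ids <- names(net$branches)
  r_lin <- stats::setNames(vapply(net$branches, function(b)
    segment_resistance(b$s, b$r, fluid), numeric(1)), ids)
  cum_r <- lapply(net$branches, function(b)
    cumulative_resistance(b$s, b$r, fluid))
  tgrid <- seq(0, T, length.out = n_t)
  has_state <- vapply(net$outlets, inherits, logical(1), "windkessel3")
  states <- stats::setNames(rep(0, length(net$outlets)), names(net$outlets))
  n_cycles <- if (any(has_state)) cycles else 1
  prev_pin <- NULL
  P_in <- numeric(n_t)
  Qmat <- matrix(0, length(ids), n_t, dimnames = list(ids, NULL))
  Pup <- matrix(0, length(ids), n_t, dimnames = list(ids, NULL))
  for (cy in seq_len(n_cycles)) {
    for (k in seq_len(n_t)) {
      qk <- Q_in(tgrid[k])
      out_aff <- lapply(names(net$outlets), function(nm)
        outlet_affine(net$outlets[[nm]], states[nm]))
      names(out_aff) <- names(net$outlets)
      r_extra <- stats::setNames(rep(0, length(ids)), ids)
      res_hist <- numeric(0)
      sol <- NULL
      for (it in seq_len(max_iter)) {
        sol <- solve_instant(net, qk, r_lin, r_extra, out_aff)
        r_new <- r_extra
        for (id in ids) {
          st <- net$branches[[id]]$stenosis
          if (!is.null(st)) {
            q_mm3 <- abs(sol$Q[id]) * 1e9
            dp <- stenosis_extra_loss(st$A_min, st$A_ref, q_mm3, fluid,
                                      Kt = st$Kt)
            r_new[id] <- if (abs(sol$Q[id]) > 1e-300)
              dp / abs(sol$Q[id]) else 0
          }
        }
        res <- max(abs(r_new - r_extra) * abs(sol$Q)) /
          max(abs(sol$P_up[net$root]), 1)
        res_hist <- c(res_hist, res)
        r_extra <- 0.7 * r_new + 0.3 * r_extra
        if (res < 1e-8) break
        if (it == max_iter)
          stop("stenosis fixed point did not converge; residual history: ",
               paste(signif(utils::tail(res_hist, 5), 3), collapse = ", "))
      }
      P_in[k] <- sol$P_up[net$root]
      Qmat[, k] <- sol$Q[ids]
      Pup[, k] <- sol$P_up[ids]
      # advance stateful outlets to the next instant
      if (any(has_state) && k < n_t) {
        dt <- tgrid[k + 1] - tgrid[k]
        for (nm in names(net$outlets)[has_state]) {
          o <- net$outlets[[nm]]
          tau <- o$Rd * o$C
          dec <- exp(-dt / tau)
          states[nm] <- states[nm] * dec +
            o$Rd * (1 - dec) * sol$Q[nm]
        }
      }
    }
    if (!is.null(prev_pin)) {
      d <- max(abs(P_in - prev_pin)) / max(max(abs(P_in)), 1e-12)
      if (d < 1e-3) break
      if (cy == n_cycles)
        stop(sprintf("pressure field not periodic after %d cycles (%.3g)",
                     cy, d))
    }
    prev_pin <- P_in
  }
  branches <- list()
  for (id in ids) {
    b <- net$branches[[id]]
    n_s <- length(b$s)
    P <- matrix(0, n_s, n_t)
    for (k in seq_len(n_t)) {
      P[, k] <- Pup[id, k] - Qmat[id, k] * cum_r[[id]]
      st <- b$stenosis
      if (!is.null(st)) {
        q_mm3 <- abs(Qmat[id, k]) * 1e9
        dp <- stenosis_extra_loss(st$A_min, st$A_ref, q_mm3, fluid,
                                  Kt = st$Kt)
        P[b$s >= st$s_pos, k] <- P[b$s >= st$s_pos, k] -
          sign(Qmat[id, k]) * dp
      }
    }
    branches[[id]] <- list(s = b$s, r = b$r, P = P, Q = Qmat[id, ])
  }
  structure(list(t = tgrid, P_inlet = P_in, branches = branches),
            class = "pressure_solution")
}

#' Time average of a sampled pressure field over one cycle
#'
#' Trapezoid time integral divided by the cycle duration; accepts a
#' vector (one waveform) or a matrix with time in columns.
#'
#' @param P pressures, vector of length n_t or matrix (n_s x n_t).
#' @param t time grid (s) spanning the full final cycle.
#' @return scalar or per-row vector of time-averaged pressure.
#' @export
time_average <- function(P, t) {
  dur <- t[length(t)] - t[1]
  if (is.matrix(P)) {
    apply(P, 1, function(row) pracma::trapz(t, row)) / dur
  } else {
    pracma::trapz(t, P) / dur
  }
}

#' Fractional flow reserve from time-averaged pressures
#'
#' `FFR = P_bar_d / P_bar_a`: the ratio of time-averaged pressure distal
#' to the lesion to the time-averaged aortic pressure. Both pressures
#' must be in the same (positive) units.
#'
#' @param P_bar_d time-averaged distal pressure.
#' @param P_bar_a time-averaged aortic (proximal reference) pressure.
#' @param location_s arc position of the distal evaluation point (mm),
#'   for reporting.
#' @return object of class `ffr_result` with `ffr`, `P_bar_d`,
#'   `P_bar_a`, `location_s`.
#' @export
compute_ffr <- function(P_bar_d, P_bar_a, location_s = NA_real_) {
  if (P_bar_d <= 0 || P_bar_a <= 0) stop("pressures must be positive")
  structure(list(ffr = P_bar_d / P_bar_a, P_bar_d = P_bar_d,
                 P_bar_a = P_bar_a, location_s = location_s),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("FFR = %.3f (P_d = %.4g, P_a = %.4g%s)\n", x$ffr,
              x$P_bar_d, x$P_bar_a,
              if (is.finite(x$location_s))
                sprintf(" at s = %.1f mm", x$location_s) else ""))
  invisible(x)
}

#' FFR from a network pressure solution
#'
#' Time-averages the pressure field of the final cycle and evaluates
#' `P_bar_d / P_bar_a` with `P_bar_a` the time-averaged inlet (aortic
#' ostium) pressure. The default distal location is one lumen diameter
#' beyond the minimal-radius point of the branch; pass `location_s` to
#' override (the choice of sampling point is a reporting convention, not
#' part of the pressure model).
#'
#' @param sol a `pressure_solution`.
#' @param branch branch id (default: the root branch).
#' @param location_s distal arc position (mm) or NULL for the default.
#' @return an `ffr_result`.
#' @export
ffr_from_solution <- function(sol, branch = names(sol$branches)[1],
                              location_s = NULL) {
  br <- sol$branches[[branch]]
  if (is.null(br)) stop("unknown branch: ", branch)
  pbar <- time_average(br$P, sol$t)
  pa <- time_average(sol$P_inlet, sol$t)
  if (is.null(location_s)) {
    i_min <- which.min(br$r)
    target <- br$s[i_min] + 2 * br$r[i_min]
    location_s <- min(max(br$s), target)
  }
  pd <- stats::approx(br$s, pbar, xout = location_s, rule = 2)$y
  compute_ffr(pd, pa, location_s = location_s)
}
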