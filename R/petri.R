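## Deterministic continuous Petri-net engine.
##
## Places carry non-negative real markings (tokens); transitions fire
## continuously with mass-action or Michaelis-Menten rate laws; standard arcs
## carry stoichiometric weights; inhibitory arcs suppress a transition once
## the source marking reaches a threshold (hard switch, the convention of
## continuous-net tools) or attenuate it smoothly (Hill-type option).  The
## marking ODE dm/dt = (post - pre) . flux is integrated with an adaptive
## Dormand-Prince RK45 scheme; negative markings are prevented by gating the
## flux of emptying transitions at the boundary rather than by clipping.

#' Construct a hybrid (continuous) Petri net
#'
#' @param places data.frame with columns `name`, `initial` (marking >= 0).
#' @param transitions data.frame with columns `name`, `type`
#'   (`"mass_action"` or `"michaelis_menten"`), `k` (mass-action rate),
#'   `Vmax`, `Km` (MM parameters; `NA` where unused), and optional `source`
#'   (logical: transition deliberately has no pre-places).
#' @param arcs data.frame with columns `place`, `transition`, `direction`
#'   (`"pre"` or `"post"`), `weight` (> 0).
#' @param inhibitory_arcs data.frame with columns `place`, `transition`,
#'   `threshold` (> 0); may be empty.
#' @return object of class `pn_net`.
#' @export
hybrid_petri_net <- function(places, transitions, arcs,
                             inhibitory_arcs = NULL) {
  if (is.null(inhibitory_arcs)) {
    inhibitory_arcs <- data.frame(place = character(0),
                                  transition = character(0),
                                  threshold = numeric(0))
  }
  nt <- nrow(transitions)
  if (is.null(transitions$source)) transitions$source <- rep(FALSE, nt)
  if (is.null(transitions$k)) transitions$k <- rep(NA_real_, nt)
  if (is.null(transitions$Vmax)) transitions$Vmax <- rep(NA_real_, nt)
  if (is.null(transitions$Km)) transitions$Km <- rep(NA_real_, nt)
  net <- structure(list(places = places, transitions = transitions,
                        arcs = arcs, inhibitory_arcs = inhibitory_arcs),
                   class = "pn_net")
  net
}

#' @export
print.pn_net <- function(x, ...) {
  cat("<pn_net> ", nrow(x$places), " places, ", nrow(x$transitions),
      " transitions, ", nrow(x$arcs), " arcs (",
      nrow(x$inhibitory_arcs), " inhibitory)\n", sep = "")
  invisible(x)
}

#' Validate a Petri net
#'
#' @param net a [hybrid_petri_net()].
#' @return character vector of violations, empty iff the net is valid; each
#'   violation names the offending element.
#' @export
validate_net <- function(net) {
  v <- character(0)
  p <- net$places; tr <- net$transitions; a <- net$arcs; ih <- net$inhibitory_arcs
  for (nm in p$name[duplicated(p$name)]) {
    v <- c(v, paste0("duplicate place name '", nm, "'"))
  }
  for (nm in tr$name[duplicated(tr$name)]) {
    v <- c(v, paste0("duplicate transition name '", nm, "'"))
  }
  if (nrow(p) && any(!is.finite(p$initial) | p$initial < 0)) {
    for (nm in p$name[!is.finite(p$initial) | p$initial < 0]) {
      v <- c(v, paste0("negative or non-finite initial marking on place '", nm, "'"))
    }
  }
  if (nrow(tr)) {
    bad_type <- !tr$type %in% c("mass_action", "michaelis_menten")
    for (nm in tr$name[bad_type]) {
      v <- c(v, paste0("unknown rate law on transition '", nm, "'"))
    }
    ma <- tr$type == "mass_action"
    for (nm in tr$name[ma & (is.na(tr$k) | tr$k < 0)]) {
      v <- c(v, paste0("mass-action transition '", nm, "' needs k >= 0"))
    }
    mm <- tr$type == "michaelis_menten"
    for (nm in tr$name[mm & (is.na(tr$Vmax) | tr$Vmax < 0 |
                             is.na(tr$Km) | tr$Km <= 0)]) {
      v <- c(v, paste0("Michaelis-Menten transition '", nm,
                       "' needs Vmax >= 0 and Km > 0"))
    }
  }
  check_ref <- function(df, col, universe, what) {
    for (nm in setdiff(unique(df[[col]]), universe)) {
      v <<- c(v, paste0(what, " references unknown ", col, " '", nm, "'"))
    }
  }
  if (nrow(a)) {
    check_ref(a, "place", p$name, "arc")
    check_ref(a, "transition", tr$name, "arc")
    if (any(!a$direction %in% c("pre", "post"))) {
      v <- c(v, "arc direction must be 'pre' or 'post'")
    }
    if (any(!is.finite(a$weight) | a$weight <= 0)) {
      v <- c(v, "arc weights must be positive")
    }
  }
  if (nrow(ih)) {
    check_ref(ih, "place", p$name, "inhibitory arc")
    check_ref(ih, "transition", tr$name, "inhibitory arc")
    if (any(!is.finite(ih$threshold) | ih$threshold <= 0)) {
      v <- c(v, "inhibitory-arc thresholds must be positive")
    }
  }
  if (nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      pre <- a$place[a$transition == tr$name[i] & a$direction == "pre"]
      if (!length(pre) && !isTRUE(tr$source[i])) {
        v <- c(v, paste0("transition '", tr$name[i],
                         "' has no pre-places and is not flagged as source"))
      }
      if (tr$type[i] == "michaelis_menten" && length(pre) != 1L) {
        v <- c(v, paste0("Michaelis-Menten transition '", tr$name[i],
                         "' must have exactly one pre-place"))
      }
    }
  }
  v
}

# compiled view used by the integrator
.compile_net <- function(net) {
  p <- net$places; tr <- net$transitions; a <- net$arcs
  np <- nrow(p); nt <- nrow(tr)
  pidx <- stats::setNames(seq_len(np), p$name)
  pre_w <- matrix(0, np, nt, dimnames = list(p$name, tr$name))
  post_w <- matrix(0, np, nt, dimnames = list(p$name, tr$name))
  for (k in seq_len(nrow(a))) {
    i <- pidx[[a$place[k]]]
    j <- which(tr$name == a$transition[k])
    if (a$direction[k] == "pre") pre_w[i, j] <- pre_w[i, j] + a$weight[k]
    else post_w[i, j] <- post_w[i, j] + a$weight[k]
  }
  inh <- lapply(seq_len(nt), function(j) {
    sel <- net$inhibitory_arcs$transition == tr$name[j]
    list(place = pidx[net$inhibitory_arcs$place[sel]],
         threshold = net$inhibitory_arcs$threshold[sel])
  })
  list(p = p, tr = tr, pre_w = pre_w, post_w = post_w, S = post_w - pre_w,
       inh = inh, pidx = pidx)
}

.flux_vector <- function(cn, m, inhibition_mode = "hard", hill = 1) {
  nt <- nrow(cn$tr)
  m_eff <- pmax(m, 0)
  flux <- numeric(nt)
  for (j in seq_len(nt)) {
    pre <- which(cn$pre_w[, j] > 0)
    if (cn$tr$type[j] == "mass_action") {
      f <- cn$tr$k[j]
      if (length(pre)) f <- f * prod(m_eff[pre]^cn$pre_w[pre, j])
    } else {
      s <- pre[1]
      f <- cn$tr$Vmax[j] * m_eff[s] / (cn$tr$Km[j] + m_eff[s])
    }
    # gate emptying transitions at the boundary
    if (length(pre) && any(m[pre] <= 0)) f <- 0
    ia <- cn$inh[[j]]
    if (length(ia$place)) {
      if (inhibition_mode == "hard") {
        if (any(m_eff[ia$place] >= ia$threshold)) f <- 0
      } else {
        f <- f * prod(ia$threshold^hill /
                        (ia$threshold^hill + m_eff[ia$place]^hill))
      }
    }
    flux[j] <- f
  }
  flux
}

#' Instantaneous flux of one transition
#'
#' @param net a [hybrid_petri_net()].
#' @param marking named numeric vector covering all places.
#' @param transition transition name.
#' @param inhibition_mode `"hard"` (flux 0 once any inhibitor marking reaches
#'   its threshold) or `"smooth"` (Hill-type factor
#'   `threshold^n / (threshold^n + m^n)` per inhibitory arc).
#' @param inhibition_hill Hill exponent n of the smooth mode; as n grows the
#'   smooth factor converges pointwise to the hard switch (except exactly at
#'   the threshold).
#' @return flux in tokens per time unit.
#' @export
transition_rate <- function(net, marking, transition,
                            inhibition_mode = c("hard", "smooth"),
                            inhibition_hill = 1) {
  inhibition_mode <- match.arg(inhibition_mode)
  viol <- validate_net(net)
  if (length(viol)) stop("invalid net:\n  ", paste(viol, collapse = "\n  "))
  if (!all(net$places$name %in% names(marking))) {
    stop("marking must be defined for all places")
  }
  j <- which(net$transitions$name == transition)
  if (!length(j)) stop("unknown transition '", transition, "'")
  cn <- .compile_net(net)
  m <- as.numeric(marking[net$places$name])
  .flux_vector(cn, m, inhibition_mode, inhibition_hill)[j]
}

# Dormand-Prince 5(4) tableau
.dp_A <- matrix(0, 7, 7)
.dp_A[2, 1] <- 1/5
.dp_A[3, 1:2] <- c(3/40, 9/40)
.dp_A[4, 1:3] <- c(44/45, -56/15, 32/9)
.dp_A[5, 1:4] <- c(19372/6561, -25360/2187, 64448/6561, -212/729)
.dp_A[6, 1:5] <- c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656)
.dp_A[7, 1:6] <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)

#' Simulate a continuous Petri net
#'
#' Deterministic integration of the marking ODE on a fixed output grid
#' (`grid_points` intervals per run, integrated exactly to each output time
#' with adaptive sub-steps).
#'
#' @param net a [hybrid_petri_net()]; must pass [validate_net()].
#' @param horizon simulation span in time units (> 0).
#' @param rtol,atol relative/absolute error tolerances.
#' @param max_step largest internal step (default `horizon / grid_points`).
#' @param inhibition_mode,inhibition_hill see [transition_rate()].
#' @param grid_points number of output intervals (the grid has
#'   `grid_points + 1` times including 0).
#' @return object of class `pn_trajectory`: list with `time` (vector),
#'   `markings` (matrix, one column per place), `net`, and `solver` metadata.
#' @export
simulate_net <- function(net, horizon, rtol = 1e-6, atol = 1e-9,
                         max_step = NULL, inhibition_mode = c("hard", "smooth"),
                         inhibition_hill = 1, grid_points = 200L) {
  inhibition_mode <- match.arg(inhibition_mode)
  viol <- validate_net(net)
  if (length(viol)) stop("invalid net:\n  ", paste(viol, collapse = "\n  "))
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0")
  cn <- .compile_net(net)
  np <- nrow(cn$p)
  if (is.null(max_step)) max_step <- horizon / grid_points
  grid <- seq(0, horizon, length.out = grid_points + 1L)
  out <- matrix(NA_real_, length(grid), np,
                dimnames = list(NULL, cn$p$name))
  m <- as.numeric(cn$p$initial)
  out[1, ] <- m
  deriv <- function(m) {
    as.numeric(cn$S %*% .flux_vector(cn, m, inhibition_mode, inhibition_hill))
  }

  rk_step <- function(m, h) {
    K <- matrix(0, np, 7)
    K[, 1] <- deriv(m)
    for (s in 2:7) {
      ms <- m + h * as.numeric(K[, 1:(s - 1), drop = FALSE] %*%
                                 .dp_A[s, 1:(s - 1)])
      K[, s] <- deriv(ms)
    }
    y5 <- m + h * as.numeric(K %*% .dp_b5)
    y4 <- m + h * as.numeric(K %*% .dp_b4)
    sc <- atol + rtol * pmax(abs(m), abs(y5))
    list(y = y5, err = sqrt(mean(((y5 - y4) / sc)^2)))
  }

  # inhibitory-arc thresholds are discontinuities of the hard-switch vector
  # field; crossings are localized by bisection so the trajectory does not
  # depend on where a step happens to straddle the switch
  ev_place <- match(net$inhibitory_arcs$place, cn$p$name)
  ev_thr <- net$inhibitory_arcs$threshold
  ev_tol <- 1e-9 * pmax(1, ev_thr)
  crossed <- function(m0, m1) {
    if (inhibition_mode != "hard" || !length(ev_place)) return(FALSE)
    s0 <- m0[ev_place] - ev_thr
    s1 <- m1[ev_place] - ev_thr
    any((s0 < -ev_tol & s1 > ev_tol) | (s0 > ev_tol & s1 < -ev_tol))
  }

  h <- max_step
  n_steps <- 0L; n_rej <- 0L
  t <- 0
  for (g in seq(2L, length(grid))) {
    t_end <- grid[g]
    while (t < t_end - 1e-12 * horizon) {
      h <- min(h, max_step, t_end - t)
      st <- rk_step(m, h)
      if (!is.finite(st$err)) {
        stop("solver failure: non-finite state at t = ", format(t))
      }
      if (st$err <= 1 || h <= 1e-12 * horizon) {
        if (st$err > 1) {
          stop("solver non-convergence at t = ", format(t),
               ": error ", format(st$err), " at minimal step")
        }
        if (crossed(m, st$y) && h > 1e-10 * horizon) {
          lo <- 0; hi <- h
          for (it in 1:60) {
            mid <- (lo + hi) / 2
            if (crossed(m, rk_step(m, mid)$y)) hi <- mid else lo <- mid
            if (hi - lo < 1e-12 * h) break
          }
          h <- hi
          st <- rk_step(m, h)
        }
        t <- t + h
        m <- pmax(st$y, 0)   # guard against O(atol) undershoot
        n_steps <- n_steps + 1L
        if (n_steps > 5e6) stop("solver non-convergence: step budget exceeded")
      } else {
        n_rej <- n_rej + 1L
        if (n_rej > 5e6) stop("solver non-convergence: rejection budget exceeded")
      }
      fac <- 0.9 * (1 / max(st$err, 1e-10))^(1 / 5)
      h <- h * min(5, max(0.2, fac))
      if (h <= 0 || !is.finite(h)) stop("solver failure: degenerate step size")
    }
    t <- t_end
    out[g, ] <- m
  }
  structure(list(time = grid, markings = out, net = net,
                 solver = list(rtol = rtol, atol = atol, max_step = max_step,
                               inhibition_mode = inhibition_mode,
                               steps = n_steps, rejected = n_rej)),
            class = "pn_trajectory")
}

#' @export
print.pn_trajectory <- function(x, ...) {
  cat("<pn_trajectory> ", length(x$time), " time points over [0, ",
      format(max(x$time)), "], ", ncol(x$markings), " places\n", sep = "")
  invisible(x)
}

#' Fold change of a place marking along a trajectory
#'
#' @param traj a `pn_trajectory`.
#' @param place place name.
#' @param mode `"final_over_initial"` or `"peak_over_initial"` (peak = max
#'   over the whole output grid).
#' @return the ratio, or `NA` (with a warning) when the initial marking is 0.
#' @export
fold_change <- function(traj, place,
                        mode = c("final_over_initial", "peak_over_initial")) {
  mode <- match.arg(mode)
  if (!place %in% colnames(traj$markings)) {
    stop("unknown place '", place, "'")
  }
  series <- traj$markings[, place]
  m0 <- series[1]
  if (m0 <= 0) {
    warning("initial marking of '", place, "' is 0; fold change undefined")
    return(NA_real_)
  }
  num <- if (mode == "final_over_initial") series[length(series)] else max(series)
  num / m0
}

#' Export a trajectory as a tidy data.frame / CSV
#'
#' @param traj a `pn_trajectory`.
#' @param path optional CSV output path.
#' @return data.frame with columns `time`, `place`, `marking`.
#' @export
trajectory_table <- function(traj, path = NULL) {
  df <- data.frame(
    time = rep(traj$time, ncol(traj$markings)),
    place = rep(colnames(traj$markings), each = length(traj$time)),
    marking = as.numeric(traj$markings),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Read / write a Petri-net spec (JSON)
#'
#' Format: `{"places": [{"name","initial"}], "transitions": [{"name","type",
#' "k","Vmax","Km","source"}], "arcs": [{"place","transition","direction",
#' "weight"}], "inhibitory_arcs": [{"place","transition","threshold"}]}`.
#'
#' @param path JSON file path.
#' @return a [hybrid_petri_net()].
#' @export
read_net <- function(path) {
  if (!file.exists(path)) stop("net file not found: ", path)
  spec <- jsonlite::fromJSON(path)
  ih <- spec$inhibitory_arcs
  if (is.null(ih) || (is.data.frame(ih) && !nrow(ih))) ih <- NULL
  hybrid_petri_net(as.data.frame(spec$places),
                   as.data.frame(spec$transitions),
                   as.data.frame(spec$arcs),
                   if (!is.null(ih)) as.data.frame(ih))
}

#' @rdname read_net
#' @param net a [hybrid_petri_net()].
#' @export
write_net <- function(net, path) {
  spec <- list(places = net$places, transitions = net$transitions,
               arcs = net$arcs, inhibitory_arcs = net$inhibitory_arcs)
  if (!is.null(net$comment)) spec <- c(list(comment = net$comment), spec)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
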