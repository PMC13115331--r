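# Synthetic forearm phantoms and session simulation.
#
# Gesture-evoked muscle activity is emulated as circular conductivity
# inclusions at the stylized angular positions of named forearm muscles
# (electrode 0 sits over the extensor carpi radialis, so angles are relative
# to it). The static anatomy (radius and ulna as low-conductivity discs)
# breaks the rotational symmetry of the disk, which is what makes armband
# rotation a genuine confounder.

# stylized muscle angles (radians) around the forearm cross-section
muscle_angles <- c(
  ecr = 0.0,    epl = 0.35, ei = 0.7,   ed = 1.22,  ecu = 1.75,
  fcu = 4.54,   fdp = 4.01, fds = 3.49, pt = 3.32,  fcr = 2.97,
  fpl = 2.62,   br = 5.76
)

inclusion <- function(muscle, contrast, radius = 0.16, r_pos = 0.58) {
  ang <- muscle_angles[[muscle]]
  data.frame(muscle = muscle, x = r_pos * cos(ang), y = r_pos * sin(ang),
             radius = radius, contrast = contrast)
}

#' Gesture conductivity templates
#'
#' Builds the nine gesture templates as sets of circular conductivity
#' inclusions over named forearm muscles. "rest" has no inclusions. "power"
#' and "thumb" deliberately share three of four inclusions, so their
#' steady-state voltage patterns are similar while their transition
#' dynamics differ (different per-inclusion onset lags).
#'
#' With a `participant_seed`, template geometry is jittered (centres,
#' radii, contrasts) and per-inclusion onset lags are drawn uniformly on
#' [0, 0.3] s, emulating between-participant variation; without a seed the
#' canonical templates with zero lags are returned.
#'
#' @param participant_seed Optional integer seed for participant-specific
#'   geometry jitter and onset lags.
#' @return Named list (one per gesture) of objects of class
#'   `gesture_template`: list with `gesture` and `inclusions` (data frame
#'   with columns muscle, x, y, radius, contrast, lag).
#' @examples
#' tpl <- gesture_templates()
#' nrow(tpl$power$inclusions) # 4
#' @export
gesture_templates <- function(participant_seed = NULL) {
  spec <- list(
    pointer    = list(c("ei", 0.25), c("fds", 0.18)),
    power      = list(c("fds", 0.30), c("fdp", 0.25), c("fcr", 0.20),
                      c("fpl", 0.20)),
    pronation  = list(c("pt", 0.30), c("fcr", 0.15), c("br", -0.10)),
    supination = list(c("br", 0.30), c("ed", 0.10), c("ecu", -0.08)),
    thumb      = list(c("fds", 0.30), c("fdp", 0.25), c("fcr", 0.20),
                      c("epl", 0.20)),
    tripod     = list(c("fds", 0.20), c("fpl", 0.20), c("ei", 0.10)),
    victory    = list(c("ei", 0.20), c("ed", 0.20), c("fdp", 0.10)),
    open       = list(c("ed", 0.30), c("ecr", 0.20), c("ecu", 0.15)),
    rest       = list()
  )
  build <- function(gesture) {
    rows <- spec[[gesture]]
    inc <- if (length(rows) == 0) {
      data.frame(muscle = character(0), x = numeric(0), y = numeric(0),
                 radius = numeric(0), contrast = numeric(0))
    } else {
      do.call(rbind, lapply(rows, function(r) {
        inclusion(r[1], as.numeric(r[2]))
      }))
    }
    inc$lag <- rep(0, nrow(inc))
    structure(list(gesture = gesture, inclusions = inc),
              class = "gesture_template")
  }
  out <- lapply(names(spec), build)
  names(out) <- names(spec)
  if (!is.null(participant_seed)) {
    out <- withr::with_seed(participant_seed, {
      lapply(out, function(tpl) {
        n <- nrow(tpl$inclusions)
        if (n > 0) {
          tpl$inclusions$x <- tpl$inclusions$x + stats::rnorm(n, 0, 0.02)
          tpl$inclusions$y <- tpl$inclusions$y + stats::rnorm(n, 0, 0.02)
          tpl$inclusions$radius <-
            tpl$inclusions$radius * (1 + stats::rnorm(n, 0, 0.05))
          tpl$inclusions$contrast <-
            tpl$inclusions$contrast * (1 + stats::rnorm(n, 0, 0.10))
          tpl$inclusions$lag <- stats::runif(n, 0, 0.3)
        }
        tpl
      })
    })
  }
  for (tpl in out) validate_template(tpl)
  out
}

validate_template <- function(tpl) {
  inc <- tpl$inclusions
  if (nrow(inc) > 0 &&
      any(sqrt(inc$x^2 + inc$y^2) + inc$radius > 1 + 1e-9)) {
    stop("template '", tpl$gesture, "' has an inclusion outside the disk")
  }
  invisible(tpl)
}

#' Baseline conductivity field of the forearm phantom
#'
#' Homogeneous muscle-like background with two low-conductivity bone discs
#' (radius and ulna). The bones are static anatomy: they anchor the angular
#' reference of the phantom so that electrode-belt rotation changes the
#' measured pattern.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma0 Background conductivity (S/m), default 0.3.
#' @param bone_sigma Bone conductivity (S/m), default 0.05.
#' @return Numeric per-element conductivity vector.
#' @export
base_conductivity <- function(mesh, sigma0 = 0.3, bone_sigma = 0.05) {
  ctr <- mesh$centroids
  sigma <- rep(sigma0, nrow(ctr))
  bones <- list(c(0.30 * cos(1.0), 0.30 * sin(1.0), 0.16),   # radius
                c(0.32 * cos(5.0), 0.32 * sin(5.0), 0.13))   # ulna
  for (b in bones) {
    inside <- (ctr[, 1] - b[1])^2 + (ctr[, 2] - b[2])^2 <= b[3]^2
    sigma[inside] <- bone_sigma
  }
  sigma
}

#' Apply a gesture template to a conductivity field
#'
#' Scales each inclusion's relative contrast by its activation and applies
#' it multiplicatively to the elements whose centroid falls inside the
#' inclusion circle: `sigma = base * (1 + activation * contrast)` there.
#'
#' @param template A `gesture_template`.
#' @param activation Scalar in [0, 1], or a vector with one activation per
#'   inclusion (transition modelling).
#' @param base Per-element baseline conductivity.
#' @param mesh An `eit_mesh`.
#' @return Per-element conductivity vector.
#' @export
make_gesture_field <- function(template, activation, base, mesh) {
  validate_template(template)
  inc <- template$inclusions
  if (any(activation < 0 | activation > 1)) {
    stop("activation must lie in [0, 1]")
  }
  sigma <- base
  if (nrow(inc) == 0) return(sigma)
  act <- rep_len(activation, nrow(inc))
  ctr <- mesh$centroids
  for (i in seq_len(nrow(inc))) {
    inside <- (ctr[, 1] - inc$x[i])^2 + (ctr[, 2] - inc$y[i])^2 <=
      inc$radius[i]^2
    sigma[inside] <- sigma[inside] * (1 + act[i] * inc$contrast[i])
  }
  sigma
}

#' Confounder models
#'
#' Constructs one of the three interference models applied during
#' evaluation blocks, or `"none"`:
#' * `limb_position`: a smooth low-amplitude background conductivity
#'   gradient along a direction (`"L"`, `"R"`, `"U"`, `"D"`) plus a small
#'   shift of all inclusion centres the same way — the limb posture changes
#'   the resting tissue configuration before any gesture happens.
#' * `time_drift`: slow multiplicative per-channel baseline drift
#'   `g(t) = 1 + A_c (1 - exp(-t / tau))`, emulating electrode-skin changes
#'   over long wear.
#' * `contact_rotation`: rigid rotation of the electrode belt by
#'   `rotation_frac` of the inter-electrode pitch (default half a pitch);
#'   voltages are re-solved on the rotated geometry.
#'
#' @param kind One of `"none"`, `"limb_position"`, `"time_drift"`,
#'   `"contact_rotation"`.
#' @param direction Limb-position direction, one of "L", "R", "U", "D".
#' @param amplitude Background-gradient amplitude (limb position,
#'   relative; default 0.015, calibrated so the posture-induced background
#'   drift is of the same order as the gesture-evoked channel changes) or
#'   drift amplitude (time drift, relative; default 0.02).
#' @param shift Inclusion-centre shift for limb position (fraction of the
#'   domain radius, default 0.01).
#' @param tau Drift time constant in seconds (default 120, a scaled-down
#'   stand-in for multi-hour wear).
#' @param rotation_frac Belt rotation as a fraction of the electrode pitch.
#' @return An object of class `eit_confounder`.
#' @export
confounder <- function(kind = c("none", "limb_position", "time_drift",
                                "contact_rotation"),
                       direction = "L", amplitude = NULL, shift = 0.01,
                       tau = 120, rotation_frac = 0.5) {
  kind <- match.arg(kind)
  amplitude <- amplitude %||% switch(kind, limb_position = 0.015,
                                     time_drift = 0.02, 0)
  if (kind == "limb_position" && !direction %in% c("L", "R", "U", "D")) {
    stop("limb position direction must be one of L, R, U, D")
  }
  structure(list(kind = kind, direction = direction, amplitude = amplitude,
                 shift = shift, tau = tau, rotation_frac = rotation_frac),
            class = "eit_confounder")
}

limb_direction <- function(direction) {
  switch(direction, L = c(-1, 0), R = c(1, 0), U = c(0, 1), D = c(0, -1))
}

#' Apply a confounder to a simulation setup or a frame stream
#'
#' Geometry-level confounders (`limb_position`, `contact_rotation`) act on a
#' setup list (`mesh`, `base`, `templates`) before forward solving;
#' `time_drift` acts on an emitted frame stream by scaling channels with the
#' drift factor at each frame's time; `"none"` is the identity for both.
#'
#' @param x A setup list with elements `mesh`, `base`, `templates`, or a
#'   frame tibble from [simulate_session()].
#' @param model An `eit_confounder`.
#' @return The perturbed setup or stream, same shape as the input.
#' @export
apply_confounder <- function(x, model) {
  if (!inherits(model, "eit_confounder")) stop("model must be a confounder")
  is_stream <- is.data.frame(x)
  switch(
    model$kind,
    none = x,
    time_drift = {
      if (!is_stream) return(x)
      v <- frame_matrix(x)
      amp <- attr(x, "drift_amplitudes")
      if (is.null(amp)) {
        stop("stream carries no per-channel drift amplitudes; ",
             "simulate with a seeded session first")
      }
      fac <- 1 + outer(1 - exp(-x$t / model$tau), amp)
      x$v <- v * fac
      x
    },
    limb_position = {
      if (is_stream) stop("limb_position acts on the setup, not a stream")
      dir <- limb_direction(model$direction)
      ctr <- x$mesh$centroids
      x$base <- x$base *
        (1 + model$amplitude * (ctr[, 1] * dir[1] + ctr[, 2] * dir[2]))
      x$templates <- lapply(x$templates, function(tpl) {
        if (nrow(tpl$inclusions) > 0) {
          tpl$inclusions$x <- tpl$inclusions$x + model$shift * dir[1]
          tpl$inclusions$y <- tpl$inclusions$y + model$shift * dir[2]
        }
        tpl
      })
      x
    },
    contact_rotation = {
      if (is_stream) stop("contact_rotation acts on the setup, not a stream")
      rot <- x$mesh$rotation +
        model$rotation_frac * 2 * pi / x$mesh$n_electrodes
      x$mesh <- build_disk_mesh(x$mesh$refinement, x$mesh$n_electrodes,
                                x$mesh$coverage, rotation = rot,
                                grading = x$mesh$grading)
      x
    }
  )
}

#' Session specification
#'
#' @param gestures Instruction list (defaults to the nine canonical
#'   gestures).
#' @param reps Repetitions per gesture (10 in training sessions, 5 in
#'   confounder blocks).
#' @param gesture_duration Instructed hold, seconds (3).
#' @param rest_interval Between-instruction rest, seconds (5).
#' @param frame_rate Frames per second (23).
#' @param noise_snr_db Additive Gaussian measurement noise level per
#'   channel, dB relative to the channel baseline (default 40; `Inf`
#'   disables noise).
#' @param seed Integer seed controlling transition durations, activation
#'   jitter, drift amplitudes and noise.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(gestures = gesture_classes(), reps = 10L,
                         gesture_duration = 3, rest_interval = 5,
                         frame_rate = 23, noise_snr_db = 40, seed = 1L) {
  stopifnot(gesture_duration > 0, rest_interval > 0, frame_rate > 0,
            reps >= 1)
  structure(list(gestures = gestures, reps = as.integer(reps),
                 gesture_duration = gesture_duration,
                 rest_interval = rest_interval, frame_rate = frame_rate,
                 noise_snr_db = noise_snr_db, seed = as.integer(seed)),
            class = "session_spec")
}

# smooth monotone activation ramp: normalized logistic, 0 at t = 0 and
# >= 0.99 at t = duration
transition_ramp <- function(t, duration) {
  f <- function(u) 1 / (1 + exp(-10 * (u - 0.5)))
  a <- (f(pmin(pmax(t / duration, 0), 1)) - f(0)) / (f(1) - f(0))
  pmin(pmax(a, 0), 1)
}

#' Instrument gain for a target baseline voltage range
#'
#' Computes the global dimensionless gain that scales raw solved boundary
#' voltages (volts) into the instrument's mV working range, calibrated so
#' the largest rest-frame channel reads 800 mV. The adjacent-drive pattern
#' spans a wide dynamic range across channels, which then covers roughly
#' 20-800 mV.
#'
#' @param mesh,base,protocol Clean (unperturbed) geometry, baseline field
#'   and protocol.
#' @return Scalar gain: `v_mV = solve_forward(...) * gain * 1000`.
#' @export
session_gain <- function(mesh, base, protocol = adjacent_protocol()) {
  v <- solve_forward(mesh, base, protocol)
  0.8 / max(abs(v))
}

#' Simulate a labelled measurement session
#'
#' Emulates one experimental block: for each gesture instruction (repeated
#' `reps` times) the stream holds a rest interval, a smooth transition into
#' the gesture (duration drawn uniformly from 0.4-1.2 s, with per-inclusion
#' onset lags), the instructed steady state, and the release back to rest.
#' Frames inside the 3 s instructed period carry the gesture label;
#' interval frames are unlabelled. Voltages are solved by the
#' finite-element forward model on the (possibly confounded) geometry,
#' scaled by the instrument gain into mV, and perturbed by per-channel
#' Gaussian noise; the time-drift confounder multiplies channels by a slow
#' drift factor.
#'
#' Activation levels during transitions are quantized to steps of 1/8
#' before solving (the resulting voltage steps sit below the measurement
#' noise floor) so repeated levels share one solve.
#'
#' @param spec A [session_spec()].
#' @param templates Gesture templates (list from [gesture_templates()]).
#' @param conf An `eit_confounder` (default none).
#' @param mesh Clean mesh.
#' @param protocol Drive protocol.
#' @param base Baseline conductivity (default [base_conductivity()]).
#' @param gain Instrument gain (default calibrated on the clean setup via
#'   [session_gain()], so confounder blocks keep the training calibration).
#' @param condition Condition label stored with every frame.
#' @return A tibble with columns `t`, `gesture` (NA outside instructed
#'   periods), `condition`, `phase` ("instructed"/"interval") and matrix
#'   column `v` (frames x 208, mV); attribute `frame_rate`.
#' @export
simulate_session <- function(spec, templates, conf = confounder("none"),
                             mesh, protocol = adjacent_protocol(),
                             base = base_conductivity(mesh), gain = NULL,
                             condition = conf$kind) {
  gain <- gain %||% session_gain(mesh, base, protocol)
  setup <- list(mesh = mesh, base = base, templates = templates)
  if (conf$kind %in% c("limb_position", "contact_rotation")) {
    setup <- apply_confounder(setup, conf)
  }
  if (conf$kind == "limb_position") {
    condition <- paste0("limb_", conf$direction)
  }

  fps <- spec$frame_rate
  n_instr <- floor(spec$gesture_duration * fps)
  n_rest <- floor(spec$rest_interval * fps)
  n_rep <- n_rest + n_instr
  n_total <- length(spec$gestures) * spec$reps * n_rep

  # solver cache over quantized activation vectors
  cache <- new.env(parent = emptyenv())
  factor_env <- new.env(parent = emptyenv())
  masks <- lapply(setup$templates, function(tpl) {
    inc <- tpl$inclusions
    ctr <- setup$mesh$centroids
    lapply(seq_len(nrow(inc)), function(i) {
      which((ctr[, 1] - inc$x[i])^2 + (ctr[, 2] - inc$y[i])^2 <=
              inc$radius[i]^2)
    })
  })
  solve_mv <- function(gesture, act_q) {
    key <- paste(gesture, paste(act_q, collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    tpl <- setup$templates[[gesture]]
    sigma <- setup$base
    msk <- masks[[gesture]]
    for (i in seq_along(msk)) {
      sigma[msk[[i]]] <- sigma[msk[[i]]] *
        (1 + act_q[i] * tpl$inclusions$contrast[i])
    }
    X <- solve_pair_fields(setup$mesh, sigma, factor_env$f)
    if (is.null(factor_env$f)) factor_env$f <- attr(X, "factor")
    ep <- electrode_potentials(setup$mesh, X)
    chs <- protocol$channels
    v <- (protocol$current_mA * 1e-3) *
      (ep[cbind(chs$mpos + 1L, chs$drive + 1L)] -
         ep[cbind(chs$mneg + 1L, chs$drive + 1L)])
    mv <- as.numeric(v) * gain * 1000
    cache[[key]] <- mv
    mv
  }

  out <- withr::with_seed(spec$seed, {
    v_rest <- solve_mv("rest", numeric(0))
    noise_sd <- if (is.infinite(spec$noise_snr_db)) rep(0, 208) else
      abs(v_rest) * 10^(-spec$noise_snr_db / 20)
    drift_amp <- if (conf$kind == "time_drift") {
      conf$amplitude * (1 + 0.5 * stats::rnorm(208))
    } else rep(0, 208)

    V <- matrix(0, n_total, 208L)
    lab <- rep(NA_character_, n_total)
    phase <- rep("interval", n_total)
    row <- 0L
    release <- NULL  # info about the previous gesture's release ramp
    for (gesture in spec$gestures) {
      tpl <- setup$templates[[gesture]]
      n_inc <- nrow(tpl$inclusions)
      for (rep_i in seq_len(spec$reps)) {
        d_up <- stats::runif(1, 0.4, 1.2)
        d_down <- stats::runif(1, 0.4, 1.2)
        act_steady <- pmin(1, pmax(0.7, 1 + stats::rnorm(1, 0, 0.05)))
        # rest interval, carrying the release of the previous gesture
        for (k in seq_len(n_rest)) {
          row <- row + 1L
          tloc <- (k - 1) / fps
          if (!is.null(release) && nrow(release$tpl$inclusions) > 0) {
            a <- release$act *
              (1 - transition_ramp(tloc - release$tpl$inclusions$lag,
                                   release$d))
            aq <- round(a * 8) / 8
            V[row, ] <- solve_mv(release$gesture, aq)
          } else {
            V[row, ] <- v_rest
          }
        }
        # instructed period: onset ramp then steady state
        for (k in seq_len(n_instr)) {
          row <- row + 1L
          tloc <- (k - 1) / fps
          if (n_inc > 0) {
            a <- act_steady *
              transition_ramp(tloc - tpl$inclusions$lag, d_up)
            aq <- round(a * 8) / 8
            V[row, ] <- solve_mv(gesture, aq)
          } else {
            V[row, ] <- v_rest
          }
          lab[row] <- gesture
          phase[row] <- "instructed"
        }
        release <- list(gesture = gesture, tpl = tpl, act = if (n_inc > 0)
          act_steady * transition_ramp(spec$gesture_duration -
                                         tpl$inclusions$lag, d_up)
          else numeric(0), d = d_down)
      }
    }
    if (any(noise_sd > 0)) {
      V <- V + matrix(stats::rnorm(length(V)), nrow(V)) *
        matrix(noise_sd, nrow(V), 208L, byrow = TRUE)
    }
    tvec <- (seq_len(n_total) - 1) / fps
    if (conf$kind == "time_drift") {
      V <- V * (1 + outer(1 - exp(-tvec / conf$tau), drift_amp))
    }
    stream <- tibble::tibble(t = tvec, gesture = lab,
                             condition = condition, phase = phase)
    stream$v <- V
    attr(stream, "drift_amplitudes") <- drift_amp
    stream
  })
  attr(out, "frame_rate") <- fps
  out
}
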