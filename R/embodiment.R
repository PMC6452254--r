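# 2D articulated bodies, environments, muscle model, receptors, and the
# embodied simulation loop coupling all controllers through shared physics.

TAXEL_REGIONS <- c("face", "hand", "foot", "other")

#' Build the insect-type robot body
#'
#' A planar (top-down) disc body with `n_legs` radially symmetric rotary
#' legs, each suspended by a return spring of elastic constant `K`.  The
#' joint angle modulates the radial foot position; one angle sensor and one
#' torque actuator per leg.  Feet press the ground in proportion to their
#' outward stroke and slide back unloaded (press-and-push grip with
#' smoothed Coulomb friction), which converts asymmetric leg oscillation
#' patterns into thrust.
#'
#' @param n_legs Number of legs (>= 3), default 12.
#' @param K Leg spring elastic constant (N m / rad).
#' @param mass Body mass (kg).
#' @param tau_max Actuator torque scale (N m) for unit controller output.
#' @return A `body_spec` object (`type = "insect"`).
#' @export
build_insect_body <- function(n_legs = 12, K = 0.08, mass = 1.0,
                              tau_max = 0.12) {
  stopifnot(n_legs >= 3, K > 0)
  leg_inertia <- 1.25e-5
  R0 <- 0.12
  joints <- data.frame(
    name = paste0("leg_", seq_len(n_legs)),
    parent = "disc", child = paste0("legseg_", seq_len(n_legs)),
    min = -1.2, max = 1.2, K = K, inertia = leg_inertia,
    stringsAsFactors = FALSE)
  segments <- data.frame(
    name = c("disc", paste0("legseg_", seq_len(n_legs))),
    mass = c(mass, rep(0.01, n_legs)),
    length = c(2 * R0, rep(0.11, n_legs)),
    radius = c(R0, rep(0.005, n_legs)),
    stringsAsFactors = FALSE)
  muscles <- data.frame(
    name = paste0("act_", seq_len(n_legs)),
    joint = seq_len(n_legs), sign = 0, # bidirectional torque actuator
    max_torque = tau_max, stringsAsFactors = FALSE)
  taxels <- data.frame(
    id = seq_len(2 * n_legs),
    segment = c(paste0("legseg_", seq_len(n_legs)), rep("disc", n_legs)),
    arc = c(rep(1, n_legs), (seq_len(n_legs) - 1) / n_legs),
    region = c(rep("foot", n_legs), rep("other", n_legs)),
    stringsAsFactors = FALSE)
  params <- list(
    n_legs = n_legs, mass = mass, I_body = 0.5 * mass * R0^2,
    body_radius = R0, leg_offset = 0.06, leg_stroke = 0.05,
    leg_inertia = leg_inertia, K = K,
    leg_damping = 2 * 0.3 * sqrt(K * leg_inertia),
    mu_grip = 0.8, load_gain = 6, v_smooth = 0.01,
    theta_max = 1.2, limit_stiffness = 5 * K,
    body_lin_damp = 0.1, body_rot_damp = 0.002,
    gravity = 9.81, tau_max = tau_max, theta_sensor_scale = 0.8,
    arena_half = Inf, wall_stiffness = 2000, wall_damping = 15,
    mu_wall = 0.2)
  body <- structure(list(type = "insect", segments = segments,
                         joints = joints, muscles = muscles,
                         taxels = taxels, params = params,
                         n_joints = n_legs, n_actuators = n_legs,
                         actuation = "direct_torque"),
                    class = "body_spec")
  validate_body_spec(body)
  body
}

#' Build the simplified 2D fetus body
#'
#' A sagittal chain of 11 segments -- head, two trunk segments and, per
#' side, upper arm, forearm+hand, thigh and shank+foot -- connected by 10
#' rotational joints, each actuated by an antagonist flexor/extensor muscle
#' pair (20 muscles).  Joint springs pull toward a flexed rest posture with
#' the hands near the face.  Skin taxels are tagged by region
#' (face/hand/foot/other); the human-like distribution concentrates 70% of
#' taxels on face, hands and feet, the uniform one allocates taxels
#' proportional to segment length.  Geometry scales monotonically with
#' gestational age.
#'
#' @param age_weeks Gestational age in weeks, in `[24, 42]`.
#' @param taxel_distribution `"humanlike"` or `"uniform"`.
#' @param taxel_count Total number of skin taxels (>= 20).
#' @return A `body_spec` object (`type = "fetus"`).
#' @export
build_fetus_body <- function(age_weeks = 32,
                             taxel_distribution = c("humanlike", "uniform"),
                             taxel_count = 300) {
  if (!is.numeric(age_weeks) || age_weeks < 24 || age_weeks > 42)
    stop("age_weeks must be in [24, 42], got ", age_weeks)
  taxel_distribution <- match.arg(taxel_distribution)
  stopifnot(taxel_count >= 20)

  sc <- 1 + 0.025 * (age_weeks - 32)   # length scale, 1.0 at 32 weeks
  msc <- sc^3                          # mass scale

  seg <- data.frame(
    name = c("trunk_lower", "trunk_upper", "head",
             "upper_arm_L", "forearm_hand_L", "upper_arm_R", "forearm_hand_R",
             "thigh_L", "shank_foot_L", "thigh_R", "shank_foot_R"),
    mass = msc * c(0.42, 0.38, 0.45, 0.05, 0.07, 0.05, 0.07,
                   0.10, 0.08, 0.10, 0.08),
    length = sc * c(0.11, 0.11, 0.10, 0.07, 0.11, 0.07, 0.11,
                    0.08, 0.11, 0.08, 0.11),
    radius = sc * c(0.035, 0.035, 0.045, 0.012, 0.010, 0.012, 0.010,
                    0.016, 0.012, 0.016, 0.012),
    stringsAsFactors = FALSE)

  # joints: parent segment, child segment, anchor (fraction along parent),
  # rest angle (flexed posture, relative to parent direction)
  jnt <- data.frame(
    name = c("spine", "neck", "shoulder_L", "elbow_L", "shoulder_R",
             "elbow_R", "hip_L", "knee_L", "hip_R", "knee_R"),
    parent = c("trunk_lower", "trunk_upper", "trunk_upper", "upper_arm_L",
               "trunk_upper", "upper_arm_R", "trunk_lower", "thigh_L",
               "trunk_lower", "thigh_R"),
    child = c("trunk_upper", "head", "upper_arm_L", "forearm_hand_L",
              "upper_arm_R", "forearm_hand_R", "thigh_L", "shank_foot_L",
              "thigh_R", "shank_foot_R"),
    anchor = c(1, 1, 0.95, 1, 0.95, 1, 0.05, 1, 0.05, 1),
    rest = c(0.25, 0.45, -2.35, 1.80, -2.25, 1.70,
             -2.45, 2.25, -2.35, 2.15),
    min = -0.9, max = 0.9,
    stringsAsFactors = FALSE)

  muscles <- data.frame(
    name = c(rbind(paste0(jnt$name, "_flex"), paste0(jnt$name, "_ext"))),
    joint = rep(seq_len(nrow(jnt)), each = 2),
    sign = rep(c(1, -1), nrow(jnt)),
    stringsAsFactors = FALSE)

  taxels <- fetus_taxels(seg, taxel_distribution, taxel_count)

  body <- structure(list(type = "fetus", segments = seg, joints = jnt,
                         muscles = muscles, taxels = taxels,
                         n_joints = nrow(jnt), n_actuators = nrow(muscles),
                         actuation = "muscle_pairs",
                         age_weeks = age_weeks, scale = sc,
                         taxel_distribution = taxel_distribution),
                    class = "body_spec")
  body <- compile_fetus(body)
  validate_body_spec(body)
  body
}

# taxel allocation by largest-remainder apportionment so counts scale
# linearly with taxel_count
apportion <- function(weights, total) {
  q <- weights / sum(weights) * total
  n <- floor(q)
  rem <- total - sum(n)
  if (rem > 0) {
    ord <- order(q - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  as.integer(n)
}

fetus_taxels <- function(seg, distribution, total) {
  # special zones: (segment, frac range, region)
  zones <- data.frame(
    segment = c("head", "forearm_hand_L", "forearm_hand_R",
                "shank_foot_L", "shank_foot_R"),
    lo = c(0.40, 0.60, 0.60, 0.60, 0.60),
    hi = 1, region = c("face", "hand", "hand", "foot", "foot"),
    stringsAsFactors = FALSE)
  place <- function(segment, lo, hi, k, region) {
    if (k <= 0) return(NULL)
    data.frame(segment = segment,
               arc = lo + (hi - lo) * (seq_len(k) - 0.5) / k,
               region = region, stringsAsFactors = FALSE)
  }
  if (distribution == "humanlike") {
    n_special <- round(0.70 * total)
    wz <- c(face = 0.25, hand = 0.125, hand = 0.125,
            foot = 0.10, foot = 0.10) / 0.70
    kz <- apportion(wz, n_special)
    special <- do.call(rbind, lapply(seq_len(nrow(zones)), function(i)
      place(zones$segment[i], zones$lo[i], zones$hi[i], kz[i],
            zones$region[i])))
    n_rest <- total - n_special
    kr <- apportion(seg$length, n_rest)
    rest <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      z <- zones[zones$segment == seg$name[i], ]
      hi <- if (nrow(z)) z$lo else 1  # keep bulk taxels off special zones
      place(seg$name[i], 0, hi, kr[i], "other")
    }))
    tx <- rbind(special, rest)
  } else {
    kr <- apportion(seg$length, total)
    tx <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      d <- place(seg$name[i], 0, 1, kr[i], "other")
      z <- zones[zones$segment == seg$name[i], ]
      if (nrow(z)) d$region[d$arc >= z$lo] <- z$region
      d
    }))
  }
  tx <- tx[order(match(tx$segment, seg$name), tx$arc), ]
  tx <- data.frame(id = seq_len(nrow(tx)), tx, row.names = NULL,
                   stringsAsFactors = FALSE)
  stopifnot(nrow(tx) == total)
  tx
}

# Precompute flat arrays for the C++ stepper: tree indices, ancestor
# matrix, joint inertias (about each joint, subtree at rest posture),
# spring constants and damping.
compile_fetus <- function(body) {
  seg <- body$segments; jnt <- body$joints; tax <- body$taxels
  ns <- nrow(seg); nj <- nrow(jnt)
  sidx <- function(nm) match(nm, seg$name)
  jp <- sidx(jnt$parent); jc <- sidx(jnt$child)
  seg_parent_joint <- rep(-1L, ns)
  seg_parent_joint[jc] <- seq_len(nj) - 1L
  # ancestor matrix: joint j on path from segment s to root
  anc <- matrix(0L, nj, ns)
  for (s in seq_len(ns)) {
    cur <- s
    while (seg_parent_joint[cur] >= 0) {
      j <- seg_parent_joint[cur] + 1L
      anc[j, s] <- 1L
      cur <- jp[j]
    }
  }
  # rest-posture forward kinematics for inertia computation
  px <- py <- ang <- numeric(ns)
  ang[1] <- pi / 2
  ord <- order(seg_parent_joint)  # root first; children follow parents here
  for (s in seq_len(ns)[-1]) {
    j <- seg_parent_joint[s] + 1L
    p <- jp[j]
    px[s] <- px[p] + jnt$anchor[j] * seg$length[p] * cos(ang[p])
    py[s] <- py[p] + jnt$anchor[j] * seg$length[p] * sin(ang[p])
    ang[s] <- ang[p] + jnt$rest[j]
  }
  comx <- px + 0.5 * seg$length * cos(ang)
  comy <- py + 0.5 * seg$length * sin(ang)
  jx <- px[jc]; jy <- py[jc]
  joint_I <- vapply(seq_len(nj), function(j) {
    subtree <- which(anc[j, ] == 1L)
    sum(seg$mass[subtree] *
          ((comx[subtree] - jx[j])^2 + (comy[subtree] - jy[j])^2 +
             seg$length[subtree]^2 / 12)) + 1e-5
  }, numeric(1))
  M <- sum(seg$mass)
  I_base <- sum(seg$mass * (comx^2 + comy^2 + seg$length^2 / 12))
  f0 <- 0.9  # passive joint resonance (Hz)
  joint_K <- joint_I * (2 * pi * f0)^2
  body$cbody <- list(
    n_seg = ns, n_joint = nj, n_tax = nrow(tax),
    seg_len = seg$length, seg_mass = seg$mass,
    seg_parent_joint = as.integer(seg_parent_joint),
    joint_parent_seg = as.integer(jp - 1L),
    joint_child_seg = as.integer(jc - 1L),
    joint_anchor = jnt$anchor, joint_rest = jnt$rest,
    joint_K = joint_K,
    joint_damp = 2 * 0.35 * sqrt(joint_K * joint_I),
    joint_fluid = 1.5 * sqrt(joint_K * joint_I),
    joint_min = rep(jnt$min, length.out = nj),
    joint_max = rep(jnt$max, length.out = nj),
    joint_I = joint_I,
    ancestor = as.integer(anc),
    tax_seg = as.integer(sidx(tax$segment) - 1L),
    tax_frac = tax$arc,
    tax_side = rep_len(c(1, -1), nrow(tax)),  # alternating skin sides
    mass_total = M, I_base = I_base,
    limit_stiffness = 20 * max(joint_K))
  # trunk joints are weakly actuated (postural), limbs strongly
  trunk_j <- which(jnt$name %in% c("spine", "neck"))
  tq_gain <- ifelse(body$muscles$joint %in% trunk_j, 0.4, 1.6)
  body$muscles$max_torque <- tq_gain * joint_K[body$muscles$joint]
  body$muscles$theta_opt <- 0
  body$muscles$width <- 1.6
  body$muscles$damping <- 0.3 * body$cbody$joint_damp[body$muscles$joint]
  body
}

#' Validate a body specification
#'
#' Checks the joint graph is a tree rooted at the trunk/base segment, that
#' muscles reference existing joints (with at least one flexor and one
#' extensor per joint for muscle-pair bodies), and that taxel ids are
#' unique with region tags from the fixed vocabulary.
#'
#' @param body A `body_spec`.
#' @return `body`, invisibly; errors on violation.
#' @export
validate_body_spec <- function(body) {
  stopifnot(inherits(body, "body_spec"))
  seg <- body$segments; jnt <- body$joints
  if (!all(jnt$parent %in% seg$name) || !all(jnt$child %in% seg$name))
    stop("joint references unknown segment")
  # tree check: every non-root segment is the child of exactly one joint
  root <- setdiff(seg$name, jnt$child)
  if (body$type == "fetus" && !identical(root, "trunk_lower"))
    stop("joint graph must be a tree rooted at the trunk")
  if (length(root) != 1 || anyDuplicated(jnt$child))
    stop("joint graph is not a tree: ", length(root), " root(s)")
  if (!all(body$muscles$joint %in% seq_len(nrow(jnt))))
    stop("muscle references non-existing joint")
  if (identical(body$actuation, "muscle_pairs")) {
    for (j in seq_len(nrow(jnt))) {
      sg <- body$muscles$sign[body$muscles$joint == j]
      if (!any(sg > 0) || !any(sg < 0))
        stop("joint ", jnt$name[j], " lacks a flexor/extensor pair")
    }
  }
  if (anyDuplicated(body$taxels$id)) stop("taxel ids not unique")
  if (!all(body$taxels$region %in% TAXEL_REGIONS))
    stop("unknown taxel region tag: ",
         setdiff(body$taxels$region, TAXEL_REGIONS)[1])
  invisible(body)
}

#' Environment specification
#'
#' Three environments: `uterus_fluid` (near-neutral buoyancy cancels
#' gravity; linear fluid drag; elastic damping membrane wall of the given
#' radius), `flat_plane` (gravity on, no fluid, penalty ground contact with
#' Coulomb-style friction), and `walled_arena` (top-down plane bounded by
#' four stiff walls, for the insect robot).
#'
#' @param kind One of `"uterus_fluid"`, `"flat_plane"`, `"walled_arena"`.
#' @param ... Overrides of the per-kind defaults (see Details).
#' @return An `environment_spec` object.
#' @export
environment_spec <- function(kind = c("uterus_fluid", "flat_plane",
                                      "walled_arena"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    uterus_fluid = list(gravity_g = 9.81, gravity_on = FALSE,
                        buoyancy = 1.0, drag_linear = 2.0, radius = 0.17,
                        wall_stiffness = 300, wall_damping = 10,
                        ground_stiffness = 0, ground_damping = 0,
                        friction_mu = 0, v_smooth = 0.01,
                        rot_damping = 2.0, fluid_pressure = 3.0,
                        fluid_pressure_dir = 0.6),
    flat_plane = list(gravity_g = 9.81, gravity_on = TRUE, buoyancy = 0,
                      drag_linear = 0, radius = Inf,
                      wall_stiffness = 0, wall_damping = 0,
                      ground_stiffness = 400, ground_damping = 6,
                      friction_mu = 0.8, v_smooth = 0.01,
                      rot_damping = 0.6, fluid_pressure = 0),
    walled_arena = list(gravity_g = 9.81, gravity_on = TRUE, buoyancy = 0,
                        drag_linear = 0, radius = Inf,
                        wall_stiffness = 2000, wall_damping = 15,
                        ground_stiffness = 0, ground_damping = 0,
                        friction_mu = 0.8, v_smooth = 0.01,
                        rot_damping = 0, fluid_pressure = 0,
                        arena_half = 0.9))
  ov <- list(...)
  bad <- setdiff(names(ov), c(names(defaults), "arena_half"))
  if (length(bad)) stop("unknown environment field: ", bad[1])
  defaults[names(ov)] <- ov
  structure(c(list(kind = kind), defaults), class = "environment_spec")
}

#' Uterus radius that fits a given fetus body
#'
#' Radius of the smallest circle around the body centroid containing all
#' taxels at the rest posture, inflated by `slack`.
#'
#' @param body A fetus `body_spec`.
#' @param slack Relative slack (default 0.12).
#' @return Radius in metres.
#' @export
fit_uterus <- function(body, slack = 0.08) {
  st <- initial_state(body, environment_spec("uterus_fluid"))
  kin <- fetus_kinematics(st, body$cbody)
  (1 + slack) * max(sqrt(kin$tax_x^2 + kin$tax_y^2))
}

#' Muscle torque from activation (length--tension and damping)
#'
#' `torque = sign * activation * max_torque * overlap(theta) -
#'  damping * theta_dot`, with `overlap(theta) =
#'  exp(-((theta - theta_opt)/width)^2)`, a smooth unimodal length--tension
#' factor in `(0, 1]`.
#'
#' @param activation Muscle activation in `[0, 1]`.
#' @param muscle One row of `body$muscles` (list or data.frame row).
#' @param theta Joint angle (rad, deviation from rest).
#' @param theta_dot Joint angular velocity (rad/s).
#' @return Torque in N m.
#' @export
muscle_torque <- function(activation, muscle, theta, theta_dot) {
  if (any(activation < 0 | activation > 1))
    stop("activation must be in [0, 1]")
  overlap <- exp(-((theta - muscle$theta_opt) / muscle$width)^2)
  muscle$sign * activation * muscle$max_torque * overlap -
    muscle$damping * theta_dot
}

# sum muscle torques per joint
joint_torques <- function(body, activation, theta, theta_dot) {
  m <- body$muscles
  tq <- muscle_torque(activation, m, theta[m$joint], theta_dot[m$joint])
  as.numeric(rowsum(tq, m$joint, reorder = TRUE))
}

# per-muscle receptor signals from joint state (normalized scales)
muscle_receptors <- function(body, theta, theta_dot, torque_per_muscle) {
  m <- body$muscles
  list(spindle_length = clip(-m$sign * theta[m$joint] / 1.0, -1.5, 1.5),
       spindle_velocity = clip(-m$sign * theta_dot[m$joint] / 6.0, -1.5, 1.5),
       tendon_tension = clip(abs(torque_per_muscle) / m$max_torque, 0, 1.5))
}

#' Initial body state
#'
#' For the fetus in the uterus the body is centred at the origin, trunk
#' vertical; on the flat plane it lies sideways just above the ground.  The
#' insect starts at the origin with relaxed legs.  State layout:
#' `[x, y, phi, vx, vy, omega, theta(n), thdot(n)]`.
#'
#' @param body A `body_spec`.
#' @param env An `environment_spec`.
#' @return Numeric state vector.
#' @export
initial_state <- function(body, env) {
  n <- body$n_joints
  st <- numeric(6 + 2 * n)
  if (body$type == "fetus") {
    st[3] <- pi / 2
    kin <- fetus_kinematics(st, body$cbody)
    if (env$kind == "uterus_fluid") {
      st[1] <- -mean(range(kin$tax_x))
      st[2] <- -mean(range(kin$tax_y))
    } else {
      st[3] <- 0
      kin <- fetus_kinematics(st, body$cbody)
      st[2] <- -min(kin$tax_y) + 0.004
    }
  }
  st
}

#' Advance body physics by one step (or several substeps)
#'
#' Semi-implicit Euler integration of joint and base dynamics, including
#' joint springs, fluid drag and buoyancy or gravity, wall penalty forces
#' and ground contact with smoothed Coulomb friction.  Contact normal
#' forces are recorded per taxel.
#'
#' @param body A `body_spec`.
#' @param state State vector (see [initial_state()]).
#' @param torques Per-joint active torque vector (N m).
#' @param env An `environment_spec`.
#' @param dt Physics time step in seconds, in `(0, 0.005]`.
#' @param n_sub Number of substeps of length `dt` to take.
#' @return List with the new `state`, per-taxel `tax_contact` normal forces,
#'   taxel kinematics, and total mechanical `energy`.
#' @export
physics_step <- function(body, state, torques, env, dt = 1e-3, n_sub = 1) {
  stopifnot(dt > 0, dt <= 5e-3)
  if (length(torques) != body$n_joints)
    stop("torque vector length ", length(torques),
         " does not match joint count ", body$n_joints)
  if (any(!is.finite(state))) stop("non-finite state")
  if (body$type == "insect") {
    p <- body$params
    p$arena_half <- env$arena_half %||% Inf
    p$wall_stiffness <- env$wall_stiffness
    p$wall_damping <- env$wall_damping
    insect_substeps(state, torques, p, n_sub, dt)
  } else {
    fetus_substeps(state, torques, body$cbody, unclass(env), n_sub, dt)
  }
}

#' Receptor frame from a body state
#'
#' Tactile = contact normal forces (static penalty evaluation) plus, in the
#' fluid environment, a pressure term proportional to local taxel speed,
#' plus pseudo-contact forces for self-touch (hand--face taxel proximity).
#' Spindle length/velocity are derived per muscle from joint angle and
#' velocity; tendon tension from the muscle torque magnitude.  Optionally a
#' 16x16 visual intensity image per eye.
#'
#' @param body A fetus `body_spec`.
#' @param state State vector.
#' @param env An `environment_spec`.
#' @param visual_on Render the camera images?
#' @param activation Muscle activations (for tendon tension); default 0.
#' @return A `receptor_frame` list: `tactile`, `spindle_length`,
#'   `spindle_velocity`, `tendon_tension`, optionally `visual`.
#' @export
sense <- function(body, state, env, visual_on = FALSE,
                  activation = numeric(body$n_actuators)) {
  stopifnot(body$type == "fetus")
  nj <- body$n_joints
  theta <- state[7:(6 + nj)]
  thdot <- state[(7 + nj):(6 + 2 * nj)]
  kin <- fetus_kinematics(state, body$cbody)
  tactile <- numeric(nrow(body$taxels))
  if (env$kind %in% c("flat_plane", "walled_arena")) {
    pen <- pmax(-kin$tax_y, 0)
    tactile <- tactile + env$ground_stiffness * pen
  }
  if (env$kind == "uterus_fluid") {
    r <- sqrt(kin$tax_x^2 + kin$tax_y^2)
    tactile <- tactile + env$wall_stiffness * pmax(r - env$radius, 0)
    side <- body$cbody$tax_side
    sa <- kin$seg_angle[match(body$taxels$segment, body$segments$name)]
    dynp <- pmax(kin$tax_vx * (-sin(sa) * side) +
                   kin$tax_vy * (cos(sa) * side), 0)
    tactile <- tactile +
      env$fluid_pressure * sqrt(kin$tax_vx^2 + kin$tax_vy^2) +
      env$fluid_pressure_dir * dynp
  }
  tactile <- tactile + self_touch_forces(body, kin)
  tq <- muscle_torque(activation, body$muscles,
                      theta[body$muscles$joint], thdot[body$muscles$joint])
  out <- list(tactile = tactile,
              spindle_length = muscle_receptors(body, theta, thdot, tq)$spindle_length,
              spindle_velocity = muscle_receptors(body, theta, thdot, tq)$spindle_velocity,
              tendon_tension = clip(abs(tq) / body$muscles$max_torque, 0, 1.5))
  if (visual_on) out$visual <- render_vision(body, state)
  class(out) <- "receptor_frame"
  out
}

# pseudo-contact forces between hand and face taxels (self-touch);
# the threshold is the sum of hand and head segment radii (skin surfaces)
self_touch_forces <- function(body, kin, d_touch = NULL, k_touch = 150) {
  sc <- body$scale %||% 1
  if (is.null(d_touch)) d_touch <- 0.057 * sc
  reg <- body$taxels$region
  ih <- which(reg == "hand"); jf <- which(reg == "face")
  if (!length(ih) || !length(jf)) return(numeric(length(reg)))
  self_touch_cpp(kin$tax_x, kin$tax_y, ih - 1L, jf - 1L, d_touch, k_touch)
}

#' Render the 16x16 camera images
#'
#' Two simple eye models in the head looking along the face normal.  The
#' square field of view in front of the face is rasterized: image axes are
#' lateral position and depth; pixels covered by a body segment get
#' intensity 1 (distance-shaded).  Body parts behind the head do not
#' appear.
#'
#' @param body A fetus `body_spec`.
#' @param state State vector.
#' @param res Image resolution per side.
#' @return List of two `res x res` matrices (`left`, `right`), values in
#'   `[0, 1]`.
#' @export
render_vision <- function(body, state, res = 16) {
  kin <- fetus_kinematics(state, body$cbody)
  hs <- match("head", body$segments$name)
  # eye at mid-head; face normal points "front" (rotate head axis by -90 deg)
  a <- kin$seg_angle[hs]
  ex <- kin$seg_x[hs] + 0.5 * body$segments$length[hs] * cos(a)
  ey <- kin$seg_y[hs] + 0.5 * body$segments$length[hs] * sin(a)
  nx <- cos(a - pi / 2); ny <- sin(a - pi / 2)   # depth axis (out of face)
  lx <- cos(a); ly <- sin(a)                     # lateral axis
  win <- 0.22 * (body$scale %||% 1)
  ts <- seq(0, 1, length.out = 24)
  other <- seq_len(nrow(body$segments))[-hs]
  pxs <- as.numeric(vapply(other, function(s)
    kin$seg_x[s] + ts * body$segments$length[s] * cos(kin$seg_angle[s]),
    numeric(24)))
  pys <- as.numeric(vapply(other, function(s)
    kin$seg_y[s] + ts * body$segments$length[s] * sin(kin$seg_angle[s]),
    numeric(24)))
  img <- function(off) {
    m <- matrix(0, res, res)
    cx <- ex + off * lx; cy <- ey + off * ly
    u <- (pxs - cx) * nx + (pys - cy) * ny          # depth, >0 in front
    v <- (pxs - cx) * lx + (pys - cy) * ly          # lateral
    keep <- u > 0.01 & u < win & abs(v) < win / 2
    if (any(keep)) {
      i <- pmin(pmax(ceiling(u[keep] / win * res), 1), res)
      j <- pmin(pmax(ceiling((v[keep] / win + 0.5) * res), 1), res)
      int <- 1 - u[keep] / win
      ord <- order(int)                 # later (larger) values win
      m[cbind(i, j)[ord, , drop = FALSE]] <- int[ord]
    }
    m
  }
  list(left = img(-0.01), right = img(0.01))
}

#' Simulate an embodied body--controller--environment system
#'
#' The central closed loop: at every control tick (default 10 ms) the
#' controller reads scaled sensor signals and emits motor outputs, which are
#' converted to joint torques; physics then advances in fixed 1 ms substeps.
#' All controllers interact only through the shared body dynamics.
#' Deterministic for a given seed.
#'
#' @param body A `body_spec`.
#' @param env An `environment_spec`.
#' @param controller A [chaotic_controller()] (insect) or [spinal_units()]
#'   (fetus); unit count must equal the body's actuator count.
#' @param duration Simulated seconds.
#' @param dt Physics step (s).
#' @param control_dt Control tick (s); must be a multiple of `dt`.
#' @param seed RNG seed (controller state jitter).
#' @param visual_on Record camera frames (fetus only).
#' @param plasticity Optional [spinal_weights()] updated online by Hebbian
#'   learning (fetus only).
#' @param lr Learning rate for online plasticity.
#' @param record_taxels Record taxel positions every `taxel_every` ticks.
#' @param taxel_every Tick subsampling for taxel positions (default 5).
#' @param fb_warmup Seconds before the learned spinal feedback engages
#'   (learning itself runs from the start); gives the running tactile
#'   normalizer time to settle and provides a clean behavioural baseline.
#' @return A `trajectory` object: tick times, state matrix, receptor
#'   matrices, motor outputs, energy, contacts, and bookkeeping (seed,
#'   config hash).
#' @export
simulate_embodied <- function(body, env, controller, duration,
                              dt = 1e-3, control_dt = 1e-2, seed = 1,
                              visual_on = FALSE, plasticity = NULL,
                              lr = 0.05, record_taxels = TRUE,
                              taxel_every = 5, fb_warmup = 40) {
  n_sub <- round(control_dt / dt)
  stopifnot(n_sub >= 1, duration >= 0)
  n_tick <- floor(duration / control_dt)
  if (inherits(controller, "chaotic_controller")) {
    if (controller$n != body$n_actuators)
      stop("controller has ", controller$n, " units but body has ",
           body$n_actuators, " actuators")
    return(simulate_insect(body, env, controller, n_tick, dt, control_dt,
                           n_sub, seed))
  }
  if (!inherits(controller, "spinal_units"))
    stop("unsupported controller class")
  if (controller$n != body$n_actuators)
    stop("controller has ", controller$n, " units but body has ",
         body$n_actuators, " muscles")
  simulate_fetus(body, env, controller, n_tick, dt, control_dt, n_sub,
                 seed, visual_on, plasticity, lr, record_taxels,
                 taxel_every, fb_warmup = fb_warmup)
}

simulate_insect <- function(body, env, ctrl, n_tick, dt, control_dt,
                            n_sub, seed) {
  set.seed(seed)
  n <- body$n_legs %||% body$params$n_legs
  ctrl$u <- runif(n, -0.2, 0.2)   # seeded desynchronized start
  ctrl$x <- ctrl$u
  st <- initial_state(body, env)
  p <- body$params
  p$arena_half <- env$arena_half %||% Inf
  p$wall_stiffness <- env$wall_stiffness
  p$wall_damping <- env$wall_damping
  ns <- length(st)
  states <- matrix(NA_real_, n_tick + 1, ns)
  u_rec <- matrix(NA_real_, n_tick + 1, n)
  wall <- logical(n_tick + 1)
  energy <- numeric(n_tick + 1)
  states[1, ] <- st; u_rec[1, ] <- ctrl$u
  r0 <- insect_substeps(st, numeric(n), p, 0L, dt)
  energy[1] <- r0$energy
  th_s <- body$params$theta_sensor_scale
  for (k in seq_len(n_tick)) {
    theta <- st[7:(6 + n)]
    ctrl <- chaotic_controller_step(ctrl, clip(theta / th_s, -1, 1))
    tau <- ctrl$u * body$params$tau_max
    res <- insect_substeps(st, tau, p, n_sub, dt)
    st <- res$state
    states[k + 1, ] <- st
    u_rec[k + 1, ] <- ctrl$u
    wall[k + 1] <- res$wall_contact
    energy[k + 1] <- res$energy
  }
  traj <- list(type = "insect", time = (0:n_tick) * control_dt,
               states = states, u = u_rec, wall_contact = wall,
               energy = energy, control_dt = control_dt, dt = dt,
               seed = seed, n_joints = n,
               config_hash = rlang::hash(list(body$params, unclass(env),
                                              ctrl$alpha, ctrl$eps_self,
                                              ctrl$eps_mix, seed)))
  class(traj) <- "trajectory"
  traj
}

simulate_fetus <- function(body, env, units, n_tick, dt, control_dt,
                           n_sub, seed, visual_on, plasticity, lr,
                           record_taxels, taxel_every, fb_warmup = 40) {
  set.seed(seed)
  nm <- body$n_actuators; nj <- body$n_joints; ntx <- nrow(body$taxels)
  # start each muscle oscillator at an independent random cycle phase,
  # with mild per-muscle frequency dispersion
  ph <- bvp_phase_states(nm, drive = units$base_drive,
                         rate = mean(units$osc$rate))
  units$osc$v <- ph$v
  units$osc$w <- ph$w
  units$osc$rate <- units$osc$rate * runif(nm, 0.8, 1.25)
  st <- initial_state(body, env)
  states <- matrix(NA_real_, n_tick + 1, length(st))
  tactile <- matrix(0, n_tick + 1, ntx)
  act_rec <- matrix(0, n_tick + 1, nm)
  sp_len <- matrix(0, n_tick + 1, nm)
  sp_vel <- matrix(0, n_tick + 1, nm)
  energy <- numeric(n_tick + 1)
  visual <- if (visual_on) vector("list", n_tick + 1) else NULL
  ntrec <- if (record_taxels) floor(n_tick / taxel_every) + 1 else 0
  tax_xr <- if (record_taxels) matrix(NA_real_, ntrec, ntx) else NULL
  tax_yr <- if (record_taxels) matrix(NA_real_, ntrec, ntx) else NULL
  states[1, ] <- st
  r0 <- fetus_substeps(st, numeric(nj), body$cbody, unclass(env), 0L, dt)
  energy[1] <- r0$energy
  kin0 <- fetus_kinematics(st, body$cbody)
  if (record_taxels) { tax_xr[1, ] <- kin0$tax_x; tax_yr[1, ] <- kin0$tax_y }
  if (visual_on) visual[[1]] <- render_vision(body, st)
  w_snap <- list()
  tact_prev <- numeric(ntx)
  act_prev <- numeric(nm)
  tq_prev <- numeric(nm)
  irec <- 1
  for (k in seq_len(n_tick)) {
    theta <- st[7:(6 + nj)]
    thdot <- st[(7 + nj):(6 + 2 * nj)]
    aff <- muscle_receptors(body, theta, thdot, tq_prev)
    tn <- if (!is.null(plasticity)) {
      plasticity <- normalize_update(plasticity, tact_prev, act_prev)
      normalize_tactile(plasticity, tact_prev)
    } else NULL
    # the learned feedback engages after a short warm-up (the running
    # tactile normalizer needs a few seconds of movement to settle);
    # the oscillator component is capped so base + feedback stays inside
    # the BVP oscillation window (upper Hopf near drive 1.4)
    fb_on <- !is.null(plasticity) && k * control_dt > fb_warmup
    extra <- if (fb_on)
      0.45 * spinal_drive(plasticity, tn, which = "osc") else 0
    units <- spinal_step(units, aff, control_dt, extra_drive = extra,
                         step_index = k)
    act <- units$activation
    if (fb_on) {
      # motor-pool normalization (reciprocal inhibition): the learned
      # kick is applied relative to the pool mean, so a common-mode
      # drive cannot saturate all muscles into co-contraction
      dr <- spinal_drive(plasticity, tn, which = "alpha")
      act <- clip(act + 0.6 * (dr - mean(dr)), 0, 1)
    }
    tq_prev <- muscle_torque(act, body$muscles,
                             theta[body$muscles$joint],
                             thdot[body$muscles$joint])
    jt <- as.numeric(rowsum(tq_prev, body$muscles$joint, reorder = TRUE))
    res <- fetus_substeps(st, jt, body$cbody, unclass(env), n_sub, dt)
    st <- res$state
    # tactile: contact forces + isotropic and leading-surface fluid
    # pressure + self-touch
    tact <- res$tax_contact +
      (if (env$kind == "uterus_fluid")
         env$fluid_pressure * res$tax_speed +
           env$fluid_pressure_dir * res$tax_dynp else 0)
    kin <- list(tax_x = res$tax_x, tax_y = res$tax_y)
    tact <- tact + self_touch_forces(body, kin)
    if (!is.null(plasticity))
      plasticity <- hebbian_update(plasticity,
                                   normalize_tactile(plasticity, tact),
                                   phasic_activation(plasticity, act),
                                   lr = lr)
    states[k + 1, ] <- st
    tactile[k + 1, ] <- tact
    act_rec[k + 1, ] <- act
    act_prev <- act
    sp_len[k + 1, ] <- aff$spindle_length
    sp_vel[k + 1, ] <- aff$spindle_velocity
    energy[k + 1] <- res$energy
    tact_prev <- tact
    if (record_taxels && k %% taxel_every == 0) {
      irec <- irec + 1
      tax_xr[irec, ] <- res$tax_x; tax_yr[irec, ] <- res$tax_y
    }
    if (visual_on) visual[[k + 1]] <-
      if (k %% 2 == 0) render_vision(body, st) else visual[[k]]
    if (!is.null(plasticity) && k %% 1000 == 0)
      w_snap[[length(w_snap) + 1]] <- list(tick = k,
                                           mean_w = mean(plasticity$W_alpha))
  }
  traj <- list(type = "fetus", time = (0:n_tick) * control_dt,
               states = states, tactile = tactile, activation = act_rec,
               spindle_length = sp_len, spindle_velocity = sp_vel,
               energy = energy, visual = visual,
               tax_x = tax_xr, tax_y = tax_yr, taxel_every = taxel_every,
               control_dt = control_dt, dt = dt, seed = seed,
               n_joints = nj, taxels = body$taxels,
               seg_radius = body$segments$radius[
                 match(body$taxels$segment, body$segments$name)],
               plasticity = plasticity, weight_log = w_snap,
               config_hash = rlang::hash(list(body$segments, body$joints,
                                              unclass(env), seed)))
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$type, "-", length(x$time), "ticks @",
      x$control_dt, "s, seed", x$seed, "\n")
  invisible(x)
}
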