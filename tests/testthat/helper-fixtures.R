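# Shared fixtures, generated in code at test time.

# Closed unit-cube surface mesh (12 triangles, outward-oriented).
make_cube_surface <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  tibiofit:::surface_mesh(v, f)
}

# Small deterministic cohort for geometry tests.
tiny_cohort <- function(n = 2, seed = 7) sample_cohort(n_patients = n, seed = seed)

# Desk-scale pipeline configuration used across solver tests.
desk_config <- function(...) pipeline_config(...)

# One cached reconstruction + contact model, shared by solver tests in a
# session (building it is the expensive part).
.fixture_env <- new.env(parent = emptyenv())
fixture_reconstruction <- function() {
  if (is.null(.fixture_env$rec)) {
    co <- tiny_cohort(1, seed = 3)
    .fixture_env$cfg <- desk_config()
    .fixture_env$patient <- co[1, ]
    .fixture_env$rec <- reconstruct_tibia(co[1, ], .fixture_env$cfg, seed = 11)
  }
  list(rec = .fixture_env$rec, cfg = .fixture_env$cfg,
       patient = .fixture_env$patient)
}

fixture_implanted <- function(material = "PEEK") {
  key <- paste0("st_", material)
  if (is.null(.fixture_env[[key]])) {
    fx <- fixture_reconstruction()
    cm <- contact_model(fx$rec$bone_mesh, fx$rec$implant_mesh, material,
                        fx$cfg$contact)
    st <- virtual_implantation(cm, fx$cfg$control)
    .fixture_env[[key]] <- list(cm = cm, st = st)
  }
  c(.fixture_env[[key]], fixture_reconstruction())
}

# Synthetic interface history: a patch of bone faces (triangulated grid at
# z = 0) and implant nodes whose positions follow prescribed paths.
# `motion` maps (increment t, base positions) -> displaced positions for
# the implant nodes; `bone_motion` likewise for bone nodes.
make_synthetic_history <- function(n_nodes = 12, n_inc = 10, n_cyc = 1,
                                   seed = 1,
                                   motion = NULL, bone_motion = NULL,
                                   gap0 = 0.05) {
  set.seed(seed)
  # bone grid 5 x 5 on [0, 4] x [0, 4]
  gx <- 0:4
  g <- as.matrix(expand.grid(x = gx, y = gx))
  nb <- nrow(g)
  bone0 <- cbind(g, 0)
  nid <- function(i, j) (j - 1L) * 5L + i
  faces <- NULL
  for (j in 1:4) for (i in 1:4) {
    faces <- rbind(faces,
                   c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1)),
                   c(nid(i, j), nid(i + 1, j + 1), nid(i, j + 1)))
  }
  node0 <- cbind(runif(n_nodes, 0.3, 3.7), runif(n_nodes, 0.3, 3.7),
                 gap0 + runif(n_nodes, 0, 0.02))
  total <- n_inc * n_cyc
  node_pos <- array(NA_real_, c(n_nodes, 3, total))
  bone_pos <- array(NA_real_, c(nb, 3, total))
  gap <- matrix(NA_real_, n_nodes, total)
  for (t in seq_len(total)) {
    np <- if (is.null(motion)) node0 else motion(t, node0)
    bp <- if (is.null(bone_motion)) bone0 else bone_motion(t, bone0)
    node_pos[, , t] <- np
    bone_pos[, , t] <- bp
    gap[, t] <- np[, 3] - mean(bp[, 3])
  }
  structure(list(
    node_pos = node_pos, foot_pos = node_pos, bone_pos = bone_pos,
    faces = faces, gap = gap,
    cycle = rep(seq_len(n_cyc), each = n_inc),
    n_increments = n_inc, n_cycles = n_cyc,
    slave_nodes = seq_len(n_nodes), bone_nodes = seq_len(nb),
    tributary_area = rep(1, n_nodes),
    excluded_nodes = integer(0)
  ), class = "interface_history")
}

# Rotation about z by `ang` radians (independent of package internals).
rotz <- function(ang) {
  matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# Independent brute-force oracle: for each implant node, establish the
# closest bone face at the first increment of the cycle (full scan, own
# closest-point-on-triangle code), then express the node in that face's
# co-moving orthonormal frame at every increment; the micromotion is the
# largest in-plane excursion from the cycle-start position (um).
oracle_micromotion <- function(h, cycle = h$n_cycles) {
  sel <- which(h$cycle == cycle)
  closest_pt <- function(p, a, b, cc) {
    e1 <- b - a; e2 <- cc - a
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n <- n / sqrt(sum(n^2))
    d <- p - a
    # solve for barycentric in-plane coordinates
    A <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    rhs <- c(sum(d * e1), sum(d * e2))
    uv <- solve(A, rhs)
    uv <- pmax(uv, 0); s <- sum(uv); if (s > 1) uv <- uv / s
    foot <- a + uv[1] * e1 + uv[2] * e2
    list(foot = foot, dist = sqrt(sum((p - foot)^2)))
  }
  frame_coords <- function(p, a, b, cc) {
    u1 <- (b - a) / sqrt(sum((b - a)^2))
    nv <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
            (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
            (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    nv <- nv / sqrt(sum(nv^2))
    u2 <- c(nv[2] * u1[3] - nv[3] * u1[2],
            nv[3] * u1[1] - nv[1] * u1[3],
            nv[1] * u1[2] - nv[2] * u1[1])
    c(sum((p - a) * u1), sum((p - a) * u2))
  }
  ns <- dim(h$node_pos)[1]
  out <- numeric(ns)
  bp0 <- h$bone_pos[, , sel[1]]
  for (i in seq_len(ns)) {
    p0 <- h$node_pos[i, , sel[1]]
    dists <- vapply(seq_len(nrow(h$faces)), function(f) {
      closest_pt(p0, bp0[h$faces[f, 1], ], bp0[h$faces[f, 2], ],
                 bp0[h$faces[f, 3], ])$dist
    }, 0)
    f <- which.min(dists)
    xi0 <- frame_coords(p0, bp0[h$faces[f, 1], ], bp0[h$faces[f, 2], ],
                        bp0[h$faces[f, 3], ])
    trace <- vapply(sel, function(t) {
      bpt <- h$bone_pos[, , t]
      xi <- frame_coords(h$node_pos[i, , t], bpt[h$faces[f, 1], ],
                         bpt[h$faces[f, 2], ], bpt[h$faces[f, 3], ])
      sqrt(sum((xi - xi0)^2))
    }, 0)
    out[i] <- max(trace) * 1000
  }
  out
}

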