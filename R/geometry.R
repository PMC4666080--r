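#' Ideal A-form duplex bead coordinates
#'
#' Places the `2 * n_bp` beads of an isolated double helix in local
#' coordinates with the helix axis along +z. Bead `k` of the 5' piece
#' (local rows `1:n_bp`) sits at cylindrical position
#' `(r = helix_radius, angle (k-1) * 360 / bp_per_turn, z = (k-1) * rise)`;
#' its partner (local row `n_bp + k`) at the same height, offset by the
#' phase angle. The helix is right-handed. With the default A-form
#' parameters consecutive same-piece beads are 6.29 Angstrom apart,
#' consistent with the touching-bead spacing `l_e1 = 6.30` Angstrom.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param params a [model_parameters()] object.
#' @return A `2 * n_bp` x 3 coordinate matrix (Angstrom), local indexing:
#'   row `k` pairs with row `k + n_bp`.
#' @examples
#' x <- build_a_form_duplex(1)
#' sqrt(sum((x[1, ] - x[2, ])^2)) # 2 * 10 * sin(100 deg) = 19.70 A
#' @export
build_a_form_duplex <- function(n_bp, params = model_parameters()) {
  stopifnot(n_bp >= 1)
  k <- seq_len(n_bp) - 1
  twist <- 2 * pi / params$bp_per_turn
  phi <- params$phase_angle * pi / 180
  r <- params$helix_radius
  a <- cbind(r * cos(k * twist), r * sin(k * twist), k * params$rise)
  b <- cbind(r * cos(k * twist + phi), r * sin(k * twist + phi),
             k * params$rise)
  rbind(a, b)
}

# --- initial-conformation assembly ------------------------------------------

# nesting parent of each helix: the innermost helix whose inner interval
# strictly contains this helix's outer interval (0 = exterior)
helix_parents <- function(helices) {
  nh <- nrow(helices)
  parent <- integer(nh)
  for (h in seq_len(nh)) {
    enclosing <- which(helices$a_end < helices$a_start[h] &
                       helices$b_start > helices$b_end[h])
    if (length(enclosing)) {
      width <- helices$b_start[enclosing] - helices$a_end[enclosing]
      parent[h] <- enclosing[which.min(width)]
    }
  }
  parent
}

# circle radius accommodating chords ch (solves sum of subtended angles = 2*pi)
loop_circle_radius <- function(ch) {
  lo <- max(ch) / 2 + 1e-9
  f <- function(R) sum(2 * asin(pmin(1, ch / (2 * R)))) - 2 * pi
  if (f(lo) < 0) return(lo) # few/large chords: smallest legal circle
  stats::uniroot(f, c(lo, sum(ch)), tol = 1e-10)$root
}

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# right-handed rotation taking local +z to unit vector u; local +x points
# towards `toward` (projected perpendicular to u) when given
frame_for <- function(u, toward = NULL) {
  u <- unit(u)
  a <- if (is.null(toward)) c(0, 0, 1) - u[3] * u else
    toward - sum(toward * u) * u
  if (sqrt(sum(a^2)) < 1e-6) a <- c(1, 0, 0) - u[1] * u
  a <- unit(a)
  cbind(a, cross3(u, a), u)
}

#' Rigid ideal-geometry conformation of a secondary structure
#'
#' Deterministic geometric build used as the reference for
#' [assign_equilibrium_lengths()]: every helix is an ideal A-form duplex;
#' helices are arranged in a planar radial (star) layout around their
#' parent loops; unpaired runs are placed on circular arcs of chord spacing
#' `l_e1` joining the strand endpoints they connect; terminal tails extend
#' outward at `l_e1` spacing. The inter-helix arrangement is arbitrary
#' (equilibrium properties are trajectory averages, so only the topology
#' must be exact).
#'
#' @param ss an `rna_ss` object.
#' @param params a [model_parameters()] object.
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
ideal_conformation <- function(ss, params = model_parameters()) {
  n <- ss$n_residues
  X <- matrix(NA_real_, n, 3)
  helices <- ss$helices
  nh <- nrow(helices)
  bp_chord <- 2 * params$helix_radius *
    sin(params$phase_angle * pi / 360) # paired-bead distance, 19.70 A

  if (nh == 0) { # pure loop: straight chain at l_e1 spacing
    X <- cbind((seq_len(n) - 1) * params$l_e1, 0, 0)
    return(X)
  }

  parent <- helix_parents(helices)
  children <- split(seq_len(nh), factor(parent, levels = 0:nh))
  U <- matrix(0, nh, 3) # axis direction per helix, outer -> inner end

  place_helix <- function(h, P, u, toward = NULL) {
    hx <- helices[h, ]
    n_bp <- hx$a_end - hx$a_start + 1L
    loc <- build_a_form_duplex(n_bp, params)
    glob <- loc %*% t(frame_for(u, toward)) +
      matrix(P, 2 * n_bp, 3, byrow = TRUE)
    X[hx$a_start:hx$a_end, ] <<- glob[1:n_bp, , drop = FALSE]
    X[hx$b_end:hx$b_start, ] <<- glob[(n_bp + 1):(2 * n_bp), , drop = FALSE]
    U[h, ] <<- unit(u)
  }

  # strand walk of the loop closed by helix `entry` (0 = exterior):
  # beads and child helices in strand order
  walk_elems <- function(entry) {
    if (entry == 0) { lo <- 1L; hi <- n } else {
      lo <- helices$a_end[entry] + 1L
      hi <- helices$b_start[entry] - 1L
    }
    ids <- children[[as.character(entry)]]
    elems <- list()
    i <- lo
    while (i <= hi) {
      if (length(ids) && i %in% helices$a_start[ids]) {
        cid <- ids[helices$a_start[ids] == i]
        elems[[length(elems) + 1]] <- list(type = "helix", id = cid)
        i <- helices$b_end[cid] + 1L
      } else {
        elems[[length(elems) + 1]] <- list(type = "bead", idx = i)
        i <- i + 1L
      }
    }
    elems
  }

  # circular layout of one loop: its beads and the outer anchors of its
  # child helices sit on a circle sized by their chord widths; the entry
  # helix occupies its own chord. Child helices point radially outward and
  # their inner loops are laid out recursively from their actual 3D inner
  # base-pair positions, so strand-adjacent anchors always end up adjacent.
  place_loop <- function(entry) {
    elems <- walk_elems(entry)
    if (!length(elems)) return(invisible())
    pt_type <- character(0); pt_id <- integer(0)
    for (el in elems) {
      if (el$type == "bead") {
        pt_type <- c(pt_type, "bead"); pt_id <- c(pt_id, el$idx)
      } else {
        pt_type <- c(pt_type, "ha", "hb"); pt_id <- c(pt_id, el$id, el$id)
      }
    }
    m <- length(pt_type)
    if (entry > 0) {
      pt_type <- c("anchor", pt_type, "anchor")
      pt_id <- c(helices$a_end[entry], pt_id, helices$b_start[entry])
    }
    K <- length(pt_type)
    chords <- numeric(K) # chord after point t (t = K closes the circle)
    for (t in seq_len(K)) {
      t2 <- if (t == K) 1L else t + 1L
      helix_pair <- (pt_type[t] == "ha" && pt_type[t2] == "hb" &&
                     pt_id[t] == pt_id[t2]) ||
                    (t == K && entry > 0) # entry inner pair closes the loop
      chords[t] <- if (helix_pair) bp_chord else params$l_e1
    }
    R <- loop_circle_radius(chords)

    if (entry > 0) {
      A_a <- X[helices$a_end[entry], ]
      A_b <- X[helices$b_start[entry], ]
      f_c <- unit(A_b - A_a)
      u_e <- U[entry, ]
      m_hat <- unit(u_e - sum(u_e * f_c) * f_c)
      e_ang <- 2 * asin(min(1, bp_chord / (2 * R)))
      C <- (A_a + A_b) / 2 + m_hat * sqrt(max(R^2 - (bp_chord / 2)^2, 0))
    } else {
      f_c <- c(0, 1, 0); m_hat <- c(-1, 0, 0); C <- c(0, 0, 0)
      e_ang <- 0
    }
    point_at <- function(phi) C + R * (-cos(phi) * m_hat + sin(phi) * f_c)
    radial_at <- function(phi) -cos(phi) * m_hat + sin(phi) * f_c

    ang <- numeric(K)
    ang[1] <- -e_ang / 2
    for (t in seq_len(K - 1))
      ang[t + 1] <- ang[t] - 2 * asin(min(1, chords[t] / (2 * R)))

    for (t in seq_len(K)) {
      if (pt_type[t] == "bead") X[pt_id[t], ] <<- point_at(ang[t])
    }
    h_off <- sqrt(max(R^2 - (bp_chord / 2)^2, 1))
    t <- 1L
    while (t <= K) {
      if (pt_type[t] == "ha") {
        h <- pt_id[t]
        phi_m <- (ang[t] + ang[t + 1]) / 2
        u <- radial_at(phi_m)
        P <- C + u * h_off
        place_helix(h, P, u, toward = point_at(ang[t]) - P)
        place_loop(h)
        t <- t + 2L
      } else t <- t + 1L
    }
    invisible()
  }

  roots <- children[["0"]]
  if (length(roots) == 1) {
    # single terminal stem along +x; exterior beads are tails
    place_helix(roots, c(0, 0, 0), c(1, 0, 0))
    place_loop(roots)
  } else {
    place_loop(0L)
  }

  # terminal tails (exterior unpaired runs not placed by a loop circle)
  centroid <- colMeans(X[!is.na(X[, 1]), , drop = FALSE])
  for (r in seq_len(nrow(ss$loops))) {
    s <- ss$loops$start[r]; e <- ss$loops$end[r]; nl <- ss$loops$n[r]
    if (!anyNA(X[s:e, ])) next
    anchor_left <- s > 1 && !anyNA(X[s - 1, ])
    anchor <- if (anchor_left) X[s - 1, ] else X[e + 1, ]
    dirv <- anchor - centroid
    nd <- sqrt(sum(dirv^2))
    dirv <- if (nd < 1e-8) c(1, 0, 0) else dirv / nd
    idx <- if (anchor_left) s:e else e:s
    X[idx, ] <- matrix(anchor, nl, 3, byrow = TRUE) +
      outer(seq_len(nl) * params$l_e1, dirv)
  }
  stopifnot(all(is.finite(X)))
  X
}

#' Assemble an initial full-molecule conformation
#'
#' Starts from the rigid [ideal_conformation()], adds a small seeded jitter
#' to loop and hinge beads (breaking the exact planarity of the star
#' layout), and relaxes steric clashes by capped-step energy minimization
#' under the model force field. Deterministic for a given seed.
#'
#' @param ss an `rna_ss` object.
#' @param params a [model_parameters()] object.
#' @param seed integer seed for the jitter.
#' @param relax_steps maximum minimizer iterations (0 skips relaxation).
#' @return N x 3 coordinate matrix (Angstrom).
#' @examples
#' ss <- parse_dot_bracket("((((....))))")
#' x <- assemble_initial_conformation(ss, seed = 1)
#' nrow(x) # 12
#' @export
assemble_initial_conformation <- function(ss, params = model_parameters(),
                                          seed = 1, relax_steps = 400) {
  ref <- ideal_conformation(ss, params)
  net <- assign_equilibrium_lengths(build_spring_network(ss, params), ref,
                                    params)
  X <- ref
  loop_beads <- which(ss$pairing == 0L)
  if (length(loop_beads)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    X[loop_beads, ] <- X[loop_beads, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(loop_beads), sd = 0.1),
             ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  if (relax_steps > 0) {
    conn <- connectivity_matrix(net)
    X <- cpp_minimize(X, as.matrix(net$springs[, c("i", "j", "l_e", "H")]) -
                        matrix(c(1, 1, 0, 0), nrow(net$springs), 4,
                               byrow = TRUE),
                      conn, params$eps_lj, params$sigma_lj,
                      as.integer(relax_steps), 0.01, 0.25)
  }
  dimnames(X) <- NULL
  X
}

# N x N 0/1 matrix marking sprung pairs (excluded from LJ)
connectivity_matrix <- function(net) {
  conn <- matrix(0L, net$n_beads, net$n_beads)
  conn[cbind(net$springs$i, net$springs$j)] <- 1L
  conn[cbind(net$springs$j, net$springs$i)] <- 1L
  conn
}

# --- conformation I/O -------------------------------------------------------

#' Write / read conformations as XYZ
#'
#' Plain multi-frame XYZ with 3-decimal coordinates; round-trips bit-exactly
#' at that precision. The comment line carries the frame time in ps when
#' available.
#'
#' @param x an N x 3 matrix, or a list of them (frames).
#' @param path file path.
#' @param times optional numeric vector of frame times (ps).
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns a
#'   list with `frames` (list of N x 3 matrices) and `times`.
#' @export
write_xyz <- function(x, path, times = NULL) {
  if (is.matrix(x)) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(x)) {
    m <- x[[f]]
    writeLines(as.character(nrow(m)), con)
    writeLines(if (!is.null(times)) sprintf("t= %.6g ps", times[f]) else
               sprintf("frame %d", f), con)
    writeLines(sprintf("P %.3f %.3f %.3f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0)
  pos <- 1
  while (pos <= length(lines)) {
    nb <- as.integer(lines[pos])
    cm <- lines[pos + 1]
    tm <- if (grepl("^t=", cm)) as.numeric(strsplit(cm, " +")[[1]][2]) else NA
    block <- lines[(pos + 2):(pos + 1 + nb)]
    parts <- do.call(rbind, strsplit(block, " +"))
    frames[[length(frames) + 1]] <-
      matrix(as.numeric(parts[, 2:4]), nb, 3)
    times <- c(times, tm)
    pos <- pos + 2 + nb
  }
  list(frames = frames, times = times)
}

#' Write a conformation as a pseudo-atom PDB
#'
#' One phosphorus pseudo-atom per bead; residue number equals strand
#' position. Intended for visualization of bead models.
#'
#' @param x N x 3 coordinate matrix (Angstrom).
#' @param path file path.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(sprintf(
      "ATOM  %5d  P     N A%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      i, i, x[i, 1], x[i, 2], x[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
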