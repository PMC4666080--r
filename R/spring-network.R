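#' Build the elastic network for a secondary structure
#'
#' Within every double-helical region each bead is connected by Hooke
#' springs to:
#' * its first neighbors along its helix piece (`backbone`),
#' * its second neighbors along its helix piece (`bend`),
#' * its third neighbors along its helix piece (`torsion`),
#' * its counterpart in the complementary helix piece (`basepair`),
#' * the first neighbors of its counterpart (`cross`).
#'
#' Beads in loops and hinges carry only first-neighbor springs. Neighbor
#' rules are truncated at helix boundaries (a bend/torsion spring never spans
#' into a loop), but first-neighbor springs always cross helix/loop
#' boundaries so the strand stays connected; boundary-crossing first-neighbor
#' springs are tagged `loop`. All springs share the force constant
#' `H = H_factor * kBT / l_e1^2`.
#'
#' @param ss an [secondary_structure()] (`rna_ss`) object.
#' @param params a [model_parameters()] object.
#' @return A `spring_network`: list with `springs` (data frame `i`, `j`,
#'   `kind`, `l_e`, `H`; 1-based bead indices, `i < j`, `l_e` unset until
#'   [assign_equilibrium_lengths()]) and `n_beads`.
#' @examples
#' ss <- secondary_structure(10, data.frame(a_start = 1, a_end = 5,
#'                                          b_start = 6, b_end = 10))
#' net <- build_spring_network(ss, model_parameters())
#' nrow(net$springs) # 31 springs for an isolated 5-bp duplex
#' @export
build_spring_network <- function(ss, params = model_parameters()) {
  stopifnot(inherits(ss, "rna_ss"))
  n <- ss$n_residues
  ii <- integer(0); jj <- integer(0); kind <- character(0)
  add <- function(a, b, k) {
    ii <<- c(ii, pmin(a, b)); jj <<- c(jj, pmax(a, b))
    kind <<- c(kind, rep(k, length(a)))
  }

  for (h in seq_len(nrow(ss$helices))) {
    hx <- ss$helices[h, ]
    n_bp <- hx$a_end - hx$a_start + 1L
    if (n_bp < 1L) stop("invalid topology: helix with N_bp < 1")
    a <- hx$a_start:hx$a_end          # 5' piece, strand order
    b <- hx$b_end:hx$b_start          # partner of a[k] is b[k] (antiparallel)
    for (piece in list(a, hx$b_start:hx$b_end)) {
      if (n_bp >= 2) add(piece[-n_bp], piece[-1], "backbone")
      if (n_bp >= 3) add(piece[1:(n_bp - 2)], piece[3:n_bp], "bend")
      if (n_bp >= 4) add(piece[1:(n_bp - 3)], piece[4:n_bp], "torsion")
    }
    add(a, b, "basepair")
    if (n_bp >= 2) {
      add(a[-n_bp], b[-1], "cross")   # counterpart's next neighbor
      add(a[-1], b[-n_bp], "cross")   # counterpart's previous neighbor
    }
  }

  # strand connectivity: every consecutive pair gets exactly one spring
  have <- paste(ii, jj)
  k <- seq_len(n - 1L)
  missing <- !(paste(k, k + 1L) %in% have)
  if (any(missing)) add(k[missing], k[missing] + 1L, "loop")

  springs <- data.frame(i = ii, j = jj, kind = kind,
                        l_e = NA_real_, H = params$H,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(springs[, c("i", "j")]))
    springs <- springs[!duplicated(springs[, c("i", "j")]), ]
  if (any(springs$i == springs$j))
    stop("self-spring (i, i) is invalid")
  springs <- springs[order(springs$i, springs$j), ]
  rownames(springs) <- NULL

  net <- structure(list(springs = springs, n_beads = n),
                   class = "spring_network")
  stopifnot(network_connected(net))
  net
}

network_connected <- function(net) {
  n <- net$n_beads
  if (n == 1) return(TRUE)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  adj <- split(c(net$springs$j, net$springs$i),
               c(net$springs$i, net$springs$j))
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("Elastic network: %d beads, %d springs\n", x$n_beads,
              nrow(x$springs)))
  print(table(x$springs$kind))
  invisible(x)
}

#' Assign equilibrium spring lengths from a reference conformation
#'
#' Each spring's equilibrium length `l_e` is set to the distance between its
#' beads in `ref`, normally the ideal-geometry build from
#' [ideal_conformation()], so that the springs hold the secondary structure
#' in the helical regions. First-neighbor springs then come out at
#' `l_e ~ l_e1 = 2 * sigma` (6.29 Angstrom along an ideal A-form strand).
#' Boundary-crossing first-neighbor springs (kind `loop`) are pinned to
#' `l_e1` exactly - the touching-bead strand spacing - rather than to the
#' layout-dependent reference distance, so loop beads and helix junctions
#' share one equilibrium bond length.
#'
#' @param net a `spring_network`.
#' @param ref N x 3 matrix of reference bead coordinates (Angstrom).
#' @param params a [model_parameters()] object (for the sanity bound).
#' @return The network with `springs$l_e` filled in.
#' @export
assign_equilibrium_lengths <- function(net, ref,
                                       params = model_parameters()) {
  stopifnot(inherits(net, "spring_network"), is.matrix(ref),
            nrow(ref) == net$n_beads, ncol(ref) == 3)
  d <- ref[net$springs$i, , drop = FALSE] - ref[net$springs$j, , drop = FALSE]
  le <- sqrt(rowSums(d^2))
  bad <- which(le <= 0 | le > 5 * params$l_e1)
  if (length(bad))
    stop("geometry inconsistency: spring (", net$springs$i[bad[1]], ", ",
         net$springs$j[bad[1]], ") has reference length ",
         format(le[bad[1]], digits = 4), " A")
  le[net$springs$kind == "loop"] <- params$l_e1
  net$springs$l_e <- le
  net
}

#' Export a spring network as TSV
#'
#' Columns `i`, `j`, `kind`, `l_e`, `H` (1-based bead indices, Angstrom,
#' kBT/Angstrom^2).
#'
#' @param net a `spring_network`.
#' @param path output file path.
#' @export
write_spring_network <- function(net, path) {
  utils::write.table(net$springs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
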