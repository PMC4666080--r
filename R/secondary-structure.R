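#' Secondary structure of an RNA strand
#'
#' A strand of `n_residues` nucleotides segmented into ungapped double
#' helices and unpaired runs (loops). Each helix pairs a 5' segment
#' (`a_start:a_end`) with an antiparallel 3' segment (`b_start:b_end`):
#' residue `a_start` pairs `b_end`, `a_start + 1` pairs `b_end - 1`, and so
#' on. Coordinates are 1-based inclusive strand positions.
#'
#' @param n_residues number of nucleotides in the strand.
#' @param helices data frame with columns `a_start`, `a_end`, `b_start`,
#'   `b_end` (and optionally `name`), one row per helix.
#' @return An object of class `rna_ss`: list with `n_residues`, `helices`,
#'   `pairing` (integer vector, 0 for unpaired), and `loops` (data frame of
#'   maximal unpaired runs with columns `start`, `end`, `n`).
#' @examples
#' ss <- secondary_structure(12, data.frame(a_start = 1, a_end = 4,
#'                                          b_start = 9, b_end = 12))
#' ss$pairing[1] # 12
#' @export
secondary_structure <- function(n_residues, helices) {
  stopifnot(is.numeric(n_residues), length(n_residues) == 1, n_residues >= 1)
  n_residues <- as.integer(n_residues)
  if (is.null(helices) || nrow(helices) == 0) {
    helices <- data.frame(name = character(), a_start = integer(),
                          a_end = integer(), b_start = integer(),
                          b_end = integer(), stringsAsFactors = FALSE)
  }
  if (!"name" %in% names(helices)) {
    helices$name <- if (nrow(helices)) paste0("H", seq_len(nrow(helices)))
                    else character()
  }
  helices <- helices[, c("name", "a_start", "a_end", "b_start", "b_end")]
  for (col in c("a_start", "a_end", "b_start", "b_end"))
    helices[[col]] <- as.integer(helices[[col]])

  pairing <- integer(n_residues)
  for (h in seq_len(nrow(helices))) {
    hx <- helices[h, ]
    n_bp <- hx$a_end - hx$a_start + 1L
    if (n_bp < 1L)
      stop("invalid topology: helix ", hx$name, " has fewer than 1 base pair")
    if (hx$b_end - hx$b_start + 1L != n_bp)
      stop("invalid topology: helix ", hx$name,
           " segments have unequal lengths")
    if (hx$a_start < 1L || hx$b_end > n_residues || hx$a_end >= hx$b_start)
      stop("invalid topology: helix ", hx$name, " out of range or crossed")
    a <- hx$a_start:hx$a_end
    b <- hx$b_end:hx$b_start # antiparallel partner of a
    if (any(pairing[a] != 0L) || any(pairing[b] != 0L))
      stop("invalid topology: helix ", hx$name,
           " overlaps another helix")
    pairing[a] <- b
    pairing[b] <- a
  }
  # pairing is an involution by construction; keep the check cheap and explicit
  paired <- which(pairing > 0L)
  stopifnot(all(pairing[pairing[paired]] == paired))

  loops <- unpaired_runs(pairing)
  structure(list(n_residues = n_residues, helices = helices,
                 pairing = pairing, loops = loops),
            class = "rna_ss")
}

unpaired_runs <- function(pairing) {
  r <- rle(pairing == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             n = r$lengths[keep])
}

#' @export
print.rna_ss <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d nt, %d helices, %d unpaired runs\n",
              x$n_residues, nrow(x$helices), nrow(x$loops)))
  if (nrow(x$helices)) {
    for (h in seq_len(nrow(x$helices))) {
      hx <- x$helices[h, ]
      cat(sprintf("  %-14s %d-%d : %d-%d (%d bp)\n", hx$name, hx$a_start,
                  hx$a_end, hx$b_start, hx$b_end, hx$a_end - hx$a_start + 1L))
    }
  }
  invisible(x)
}

#' Parse a dot-bracket string into a secondary structure
#'
#' Helices are maximal ungapped stacks of nested pairs: a bulge or internal
#' loop of one or more nucleotides on either strand terminates a helix.
#' Multiple bracket alphabets `()`, `[]`, `{}` are accepted, but only
#' nested (pseudoknot-free) structures are supported.
#'
#' @param text a dot-bracket string, or a path to a file whose non-comment
#'   lines concatenate to one (lines starting with `#` or `>` are skipped).
#' @return An [secondary_structure()] object.
#' @examples
#' parse_dot_bracket("((((....))))")
#' @export
parse_dot_bracket <- function(text) {
  looks_like_structure <- function(s)
    grepl("^[.()\\[\\]{}\\s]*$", s, perl = TRUE)
  if (length(text) == 1 && !looks_like_structure(text) && file.exists(text))
    text <- paste(grep("^[#>]", readLines(text), value = TRUE,
                       invert = TRUE), collapse = "")
  text <- gsub("[[:space:]]", "", paste(text, collapse = ""))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  if (n == 0) stop("empty dot-bracket string")
  openers <- c("(" = ")", "[" = "]", "{" = "}")
  bad <- which(!chars %in% c(".", names(openers), unname(openers)))
  if (length(bad))
    stop("unsupported character '", chars[bad[1]], "' at position ", bad[1])

  pairing <- integer(n)
  stacks <- list("(" = integer(), "[" = integer(), "{" = integer())
  closer_of <- stats::setNames(names(openers), unname(openers))
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% names(openers)) {
      stacks[[ch]] <- c(stacks[[ch]], i)
    } else if (ch %in% unname(openers)) {
      op <- closer_of[[ch]]
      if (length(stacks[[op]]) == 0)
        stop("unbalanced brackets: unmatched '", ch, "' at position ", i)
      j <- stacks[[op]][length(stacks[[op]])]
      stacks[[op]] <- stacks[[op]][-length(stacks[[op]])]
      pairing[i] <- j
      pairing[j] <- i
    }
  }
  for (op in names(stacks))
    if (length(stacks[[op]]))
      stop("unbalanced brackets: unmatched '", op, "' at position ",
           stacks[[op]][1])

  # crossing pairs (possible across bracket alphabets) are pseudoknots
  op <- which(pairing > seq_len(n))
  if (length(op) > 1) {
    cl <- pairing[op]
    for (k in seq_along(op)[-1]) {
      prev <- seq_len(k - 1)
      crossing <- op[prev] < op[k] & op[k] < cl[prev] & cl[prev] < cl[k]
      if (any(crossing))
        stop("unsupported feature: pseudoknot (crossing pairs at positions ",
             op[k], " and ", op[which(crossing)[1]], ")")
    }
  }

  helices <- pairs_to_helices(pairing)
  secondary_structure(n, helices)
}

# group pairs (i < j) into maximal ungapped stacks: (i, j) stacks on
# (i - 1, j + 1)
pairs_to_helices <- function(pairing) {
  n <- length(pairing)
  op <- which(pairing > seq_len(n))
  if (!length(op))
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer()))
  op <- sort(op)
  cl <- pairing[op]
  new_helix <- c(TRUE, !(op[-1] == op[-length(op)] + 1L &
                         cl[-1] == cl[-length(op)] - 1L))
  id <- cumsum(new_helix)
  a_start <- tapply(op, id, min)
  a_end <- tapply(op, id, max)
  b_start <- tapply(cl, id, min)
  b_end <- tapply(cl, id, max)
  data.frame(a_start = as.integer(a_start), a_end = as.integer(a_end),
             b_start = as.integer(b_start), b_end = as.integer(b_end))
}

#' Render a secondary structure as a dot-bracket string
#'
#' @param ss an `rna_ss` object (pseudoknot-free by construction).
#' @return A single dot-bracket string using `()`.
#' @export
as_dot_bracket <- function(ss) {
  chars <- rep(".", ss$n_residues)
  op <- which(ss$pairing > seq_len(ss$n_residues))
  chars[op] <- "("
  chars[ss$pairing[op]] <- ")"
  paste(chars, collapse = "")
}

#' Read / write a helix table
#'
#' Tab-separated file with columns `name`, `a_start`, `a_end`, `b_start`,
#' `b_end` (1-based inclusive). Lines starting with `#` are comments; a
#' comment of the form `# n_residues: N` records the strand length (otherwise
#' the strand is assumed to end at the largest paired position).
#'
#' @param path file path.
#' @param n_residues strand length; overrides any header value.
#' @return `read_helix_table()` returns an `rna_ss`;
#'   `write_helix_table()` returns `path` invisibly.
#' @export
read_helix_table <- function(path, n_residues = NULL) {
  lines <- readLines(path)
  if (is.null(n_residues)) {
    m <- grep("^#\\s*n_residues:", lines, value = TRUE)
    if (length(m))
      n_residues <- as.integer(sub("^#\\s*n_residues:\\s*", "", m[1]))
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(n_residues)) n_residues <- max(tab$b_end)
  secondary_structure(n_residues, tab)
}

#' @rdname read_helix_table
#' @param ss an `rna_ss` object to write.
#' @export
write_helix_table <- function(ss, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_residues: %d", ss$n_residues), con)
  utils::write.table(ss$helices, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
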