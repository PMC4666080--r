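#' Built-in RNA topologies
#'
#' Two study systems ship with the package:
#'
#' * `"trna_phe"` - yeast tRNA-Phe, 76 nt cloverleaf: acceptor stem (7 bp),
#'   D stem (4 bp), anticodon stem (5 bp), T stem (5 bp), three hairpin
#'   loops and a central hinge, plus the 3' tail. Comes with an
#'   [arm_definition()] for the acceptor/anticodon inter-arm angle.
#' * `"5s_rrna"` - E. coli 5S rRNA, 120 nt, five helices (I-V), two internal
#'   and two hairpin loops, one hinge. The shipped helix table is a
#'   synthetic idealized encoding of the consensus structure: bulged
#'   helices are absorbed into ungapped duplexes (see the file header in
#'   `inst/extdata` for provenance).
#'
#' @param name fixture name, `"trna_phe"` or `"5s_rrna"`.
#' @return List with `name`, `ss` (an `rna_ss`), `arms` (an
#'   `arm_definition` for tRNA, `NULL` otherwise), and `note`.
#' @examples
#' fx <- load_fixture("trna_phe")
#' fx$ss$n_residues # 76
#' @export
load_fixture <- function(name = c("trna_phe", "5s_rrna")) {
  known <- c("trna_phe", "5s_rrna")
  if (!is.character(name) || !name[1] %in% known)
    stop("unknown fixture '", name[1], "'; available: ",
         paste(known, collapse = ", "))
  name <- name[1]
  file <- switch(name,
                 trna_phe = "trna_phe_helices.tsv",
                 `5s_rrna` = "5s_rrna_synthetic_helices.tsv")
  path <- system.file("extdata", file, package = "rnabd", mustWork = TRUE)
  ss <- read_helix_table(path)
  arms <- NULL
  if (name == "trna_phe") {
    # acceptor stem: the 7-bp terminal duplex; anticodon stem: the 5-bp
    # duplex flanking the anticodon loop; hinge-proximal ends face the
    # central multiloop
    arms <- arm_definition(arm1 = c(1:7, 66:72), arm2 = c(27:31, 39:43),
                           hinge1 = c(7, 66), tip1 = c(1, 72),
                           hinge2 = c(27, 43), tip2 = c(31, 39))
  }
  note <- readLines(path)
  note <- paste(sub("^#\\s?", "", note[startsWith(note, "#")]),
                collapse = "\n")
  list(name = name, ss = ss, arms = arms, note = note)
}
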