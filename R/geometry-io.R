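# Lattice serialization: CSV (capsomer table + edge list, round-trippable)
# and PDB pseudo-atoms (one HETATM per capsomer, kind encoded in the
# residue name) for inspection in molecular graphics programs.

#' Export a capsomer lattice to CSV or PDB
#'
#' `format = "csv"` writes the capsomer table
#' (`id,kind,x,y,z,nx,ny,nz,region,ring_index`) to `file`, with the lattice
#' vectors and lattice constant in `#`-comment header lines, and the edge
#' list to `<file stem>_edges.csv`; [read_lattice_csv()] reconstructs an
#' identical lattice. `format = "pdb"` writes one HETATM pseudo-atom per
#' capsomer (residue names `PEN`/`HEX`/`POR`, chain by region). Output is
#' bit-stable for a fixed lattice.
#'
#' @param lat A `capsomer_lattice`.
#' @param file Output path.
#' @param format `"csv"` or `"pdb"`.
#' @return Invisibly, the paths written.
#' @export
export_lattice <- function(lat, file, format = "csv") {
  stopifnot(inherits(lat, "capsomer_lattice"))
  if (!is.character(format) || length(format) != 1L || !nzchar(format)) {
    stop("unknown export format: ", deparse(format), call. = FALSE)
  }
  v <- lat$architecture$vectors
  if (format == "csv") {
    hdr <- c(sprintf("# capsidkit lattice h1=%d k1=%d h2=%d k2=%d", v$h1, v$k1, v$h2, v$k2),
             sprintf("# lattice_constant=%.10g portal=%d", lat$lattice_constant,
                     as.integer(lat$architecture$has_portal)))
    con <- file(file, "w")
    writeLines(hdr, con)
    utils::write.csv(format_lattice_df(lat$capsomers), con, row.names = FALSE,
                     quote = FALSE)
    close(con)
    efile <- paste0(sub("\\.[^.]*$", "", file), "_edges.csv")
    utils::write.csv(data.frame(from = lat$edges[, 1], to = lat$edges[, 2]),
                     efile, row.names = FALSE, quote = FALSE)
    return(invisible(c(file, efile)))
  }
  if (format == "pdb") {
    cs <- lat$capsomers
    res <- c(pentamer = "PEN", hexamer = "HEX", portal = "POR")[cs$kind]
    chain <- c(cap_bottom = "B", midsection = "M", cap_top = "T")[cs$region]
    lines <- sprintf(
      "HETATM%5d  C   %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      cs$id %% 100000L, res, chain, cs$id %% 10000L, cs$x, cs$y, cs$z)
    writeLines(c(lines, "END"), file)
    return(invisible(file))
  }
  stop("unknown export format: '", format, "'", call. = FALSE)
}

format_lattice_df <- function(cs) {
  num <- c("x", "y", "z", "nx", "ny", "nz")
  for (cl in num) cs[[cl]] <- sprintf("%.10g", cs[[cl]])
  cs
}

#' Read a capsomer lattice written by [export_lattice()]
#'
#' @param file Path to the capsomer CSV; the edge list is read from
#'   `<file stem>_edges.csv`.
#' @return A `capsomer_lattice`.
#' @export
read_lattice_csv <- function(file) {
  hdr <- readLines(file, n = 2L)
  m1 <- regmatches(hdr[1], regexec("h1=(\\d+) k1=(\\d+) h2=(\\d+) k2=(\\d+)", hdr[1]))[[1]]
  m2 <- regmatches(hdr[2], regexec("lattice_constant=([0-9.eE+-]+) portal=([01])", hdr[2]))[[1]]
  if (length(m1) != 5L || length(m2) != 3L) {
    stop("not a capsidkit lattice CSV: missing header", call. = FALSE)
  }
  v <- lattice_vectors(as.integer(m1[2]), as.integer(m1[3]),
                       as.integer(m1[4]), as.integer(m1[5]))
  arch <- architecture_counts(v, has_portal = m2[3] == "1")
  cs <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  cs$ring_index <- as.integer(cs$ring_index)
  efile <- paste0(sub("\\.[^.]*$", "", file), "_edges.csv")
  ed <- utils::read.csv(efile)
  lat <- new_capsomer_lattice(arch, cs, as.matrix(ed), as.numeric(m2[2]))
  check_lattice_census(lat)
  lat
}
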