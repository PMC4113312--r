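# Readers and writers for the package's plain-text interchange formats.
# FASTA goes through Biostrings; tables are TSV with a header line and
# optional '#' provenance comments.

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a data.frame as TSV with provenance comments
#' @param df data.frame.
#' @param path output file.
#' @param provenance optional character vector written as '# ' comments.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a genotype table
#'
#' TSV with columns marker, mother, father columns, then one column per
#' progeny (alleles as \code{"a/b"}, missing \code{"-"}); a comment line
#' records each progeny's father so the family structure round-trips.
#'
#' @param table a \code{genotype_table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  pf <- attr(table, "progeny_father")
  prov <- paste0("progeny_father: ",
                 paste(names(pf), pf, sep = "=", collapse = ","))
  write_tsv(as.data.frame(table), path, provenance = prov)
}

#' Read a genotype table written by [write_genotype_table()]
#' @param path file path.
#' @return a \code{genotype_table}.
#' @export
read_genotype_table <- function(path) {
  first <- readLines(path, n = 1)
  tab <- read_tsv(path)
  pf_str <- sub("^# progeny_father: ", "", first)
  kv <- strsplit(strsplit(pf_str, ",")[[1]], "=")
  pf <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  attr(tab, "progeny_father") <- pf
  class(tab) <- c("genotype_table", "data.frame")
  tab
}

#' Write a linkage map in MAPCHART-compatible text form
#'
#' One \code{group <name>} header per group followed by
#' \code{marker<TAB>position} rows.
#'
#' @param map a \code{linkage_map}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mapchart <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(map)) {
    writeLines(paste("group", g), con)
    writeLines(sprintf("%s\t%.3f", map[[g]]$marker, map[[g]]$pos_cM), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a simulation truth record as JSON
#' @param truth a \code{sim_truth} list.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
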