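#' Repeat consensus library
#'
#' A consensus library holds one consensus sequence per repeat subfamily plus
#' a subfamily-to-family map (e.g. several HeT-A-like subfamilies collapsing
#' onto one family). With the default map every subfamily is its own family.
#'
#' @param consensus named character vector of consensus DNA sequences
#'   (names are subfamily labels)
#' @param subfamily_map data.frame with columns `subfamily` and `family`
#'   covering every name in `consensus`; defaults to the identity map
#' @return an object of class `repeat_library`
#' @export
repeat_library <- function(consensus, subfamily_map = NULL) {
  if (length(consensus) == 0) stopf("consensus library is empty")
  if (is.null(names(consensus)) || anyNA(names(consensus)) ||
      any(names(consensus) == ""))
    stopf("consensus sequences must be named by subfamily")
  if (any(nchar(consensus) == 0)) stopf("empty consensus sequence")
  if (is.null(subfamily_map)) {
    subfamily_map <- data.frame(subfamily = names(consensus),
                                family = names(consensus),
                                stringsAsFactors = FALSE)
  }
  missing <- setdiff(names(consensus), subfamily_map$subfamily)
  if (length(missing) > 0)
    stopf("subfamily map does not cover: %s", paste(missing, collapse = ", "))
  structure(list(consensus = consensus, subfamily_map = subfamily_map),
            class = "repeat_library")
}

#' @export
print.repeat_library <- function(x, ...) {
  cat(sprintf("repeat_library: %d subfamilies, %d families\n",
              length(x$consensus), length(unique(x$subfamily_map$family))))
  invisible(x)
}

#' Write a repeat library to FASTA + subfamily map TSV
#' @param library a [repeat_library()]
#' @param fasta_path output FASTA path for consensus sequences
#' @param map_path output TSV path (columns subfamily, family)
#' @export
write_repeat_library <- function(library, fasta_path, map_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(library$consensus), fasta_path)
  write.table(library$subfamily_map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, map_path))
}

#' Read a repeat library from FASTA + subfamily map TSV
#' @param fasta_path consensus FASTA path
#' @param map_path subfamily map TSV path (columns subfamily, family);
#'   `NULL` for the identity map
#' @return a [repeat_library()]
#' @export
read_repeat_library <- function(fasta_path, map_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cons <- setNames(as.character(seqs), names(seqs))
  map <- if (is.null(map_path)) NULL else
    read.table(map_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  repeat_library(cons, map)
}

# family label for each subfamily label, via the library map
map_family <- function(library, subfamily) {
  idx <- match(subfamily, library$subfamily_map$subfamily)
  library$subfamily_map$family[idx]
}
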