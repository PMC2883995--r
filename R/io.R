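#' Write / read a semantic map as TSV
#'
#' The map table has a `word` column, one column per PC (`pc1` ...), and
#' a `vector_length` column; rows follow the map's word order. The
#' per-PC summary (sd, kurtosis, cumulative variance) can be written
#' alongside with [write_map_summary].
#'
#' @param m a `semantic_map`.
#' @param path file path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   `semantic_map` (without graph or fit metadata).
#' @export
write_map <- function(m, path) {
  stopifnot(inherits(m, "semantic_map"))
  tab <- data.frame(word = m$words, m$pcs,
                    vector_length = sqrt(rowSums(m$pcs^2)))
  names(tab) <- c("word", paste0("pc", seq_len(ncol(m$pcs))),
                  "vector_length")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  pccols <- grep("^pc[0-9]+$", names(tab))
  new_semantic_map(as.character(tab$word),
                   as.matrix(tab[, pccols, drop = FALSE]))
}

#' @rdname write_map
#' @export
write_map_summary <- function(m, path) {
  utils::write.table(pc_summary(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
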