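fmt_num <- function(x) sprintf("%.12g", x)

#' Write a weight matrix as a long-format TSV
#'
#' One row per (disease, protein) pair with a nonzero weight, matching the
#' standard persisted form `disease_id  protein_id  weight`.
#'
#' @param W Disease x protein weight matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_weights_tsv <- function(W, path) {
  lines <- "#disease_id\tprotein_id\tweight"
  for (d in rownames(W)) {
    w <- W[d, ]
    nz <- which(w != 0)
    if (length(nz))
      lines <- c(lines, paste(d, colnames(W)[nz], fmt_num(w[nz]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

write_df_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  lg <- vapply(df, is.logical, logical(1))
  df[lg] <- lapply(df[lg], function(x) ifelse(x, "Y", "N"))
  lines <- c(paste0("#", paste(names(df), collapse = "\t")),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

content_hash <- function(paths, extra = "") {
  stopifnot(all(file.exists(paths)))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(unname(tools::md5sum(paths)), extra), tf)
  unname(tools::md5sum(tf))
}
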