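#' Read and write network edge lists
#'
#' Two tab-separated dialects are supported. The `signed` dialect is
#' `source<TAB>target<TAB>sign` with sign `+1` or `-1` and an optional fourth
#' `weight` column in `[0, 1]`; lines starting with `#` are comments. The
#' `dream` dialect follows DREAM-challenge gold-standard files:
#' `source<TAB>target<TAB>{0,1}`, where rows with third column 0 denote
#' explicitly absent edges (dropped on read) and all present edges are read
#' with sign `+1`.
#'
#' @param path file path
#' @param dialect `"signed"` or `"dream"`
#' @return `read_network` returns a [signed_digraph()]; `write_network`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, dialect = c("signed", "dream")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(signed_digraph(NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  min_fields <- 3L
  bad <- which(nfield < min_fields)
  if (length(bad) > 0L) {
    stop("malformed row at line ", lineno[bad[1L]], ": expected at least ",
         min_fields, " tab-separated fields")
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  third <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (any(is.na(third))) {
    stop("malformed row at line ", lineno[which(is.na(third))[1L]],
         ": non-numeric third column")
  }
  if (dialect == "dream") {
    if (!all(third %in% c(0, 1))) {
      stop("malformed row at line ", lineno[which(!third %in% c(0, 1))[1L]],
           ": dream dialect requires 0/1 in the third column")
    }
    present <- third == 1
    edges <- data.frame(from = from[present], to = to[present], sign = 1L,
                        stringsAsFactors = FALSE)
  } else {
    if (!all(third %in% c(-1, 1))) {
      stop("malformed row at line ", lineno[which(!third %in% c(-1, 1))[1L]],
           ": signed dialect requires +1/-1 in the third column")
    }
    edges <- data.frame(from = from, to = to, sign = as.integer(third),
                        stringsAsFactors = FALSE)
    if (any(nfield >= 4L)) {
      w <- rep(NA_real_, length(parts))
      has_w <- nfield >= 4L
      w[has_w] <- suppressWarnings(
        as.numeric(vapply(parts[has_w], `[[`, "", 4L)))
      if (any(has_w & is.na(w))) {
        stop("malformed row at line ", lineno[which(has_w & is.na(w))[1L]],
             ": non-numeric weight column")
      }
      w[!has_w] <- 1
      edges$weight <- w
    }
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- key[duplicated(key)]
    for (d in dups) {
      rows <- edges$sign[key == d]
      if (length(unique(rows)) > 1L) {
        stop("duplicate ordered pair with conflicting sign: ",
             gsub("\r", " -> ", d, fixed = TRUE))
      }
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  signed_digraph(edges)
}

#' @rdname read_network
#' @param g a [signed_digraph()]
#' @export
write_network <- function(g, path, dialect = c("signed", "dream")) {
  dialect <- match.arg(dialect)
  stopifnot(is_signed_digraph(g))
  e <- g$edges
  if (dialect == "dream") {
    out <- paste(e$from, e$to, 1L, sep = "\t")
  } else {
    out <- paste(e$from, e$to, sprintf("%+d", e$sign), sep = "\t")
    if ("weight" %in% names(e)) {
      out <- paste(out, format(e$weight, digits = 10, trim = TRUE),
                   sep = "\t")
    }
  }
  writeLines(out, path)
  invisible(path)
}
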