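#' Read a regulatory network from disk
#'
#' Three dialects are supported. `json` (canonical) is a single document
#' `{name, nodes:[...], edges:[...], signals:{...}}`. `tsv` is a directory (or
#' file-prefix) holding `nodes.tsv` (id, label, kind, self_mode, perturbable),
#' `edges.tsv` (source, target, sign, ...) and optionally `signals.tsv`
#' (key, value). `sif` is an import-only convenience: lines of
#' `source <+1|-1> target`; node kinds default to protein with self-sustaining
#' mode. All I/O is UTF-8.
#'
#' @param path file (json, sif) or directory/prefix (tsv).
#' @param format one of `"json"`, `"tsv"`, `"sif"`; guessed from the path
#'   extension when missing.
#' @return a validated `regnet`; node order equals declaration order.
#' @export
read_network <- function(path, format = c("json", "tsv", "sif")) {
  if (missing(format)) {
    format <- if (dir.exists(path)) "tsv"
      else switch(tolower(tools::file_ext(path)), json = "json", sif = "sif", "tsv")
  }
  format <- match.arg(format)
  switch(format,
    json = read_network_json(path),
    tsv  = read_network_tsv(path),
    sif  = read_network_sif(path))
}

read_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  signals <- as.list(doc$signals)
  regnet(doc$nodes, doc$edges, signals = signals, name = doc$name)
}

tsv_paths <- function(path) {
  if (dir.exists(path)) {
    file.path(path, c("nodes.tsv", "edges.tsv", "signals.tsv"))
  } else {
    paste0(path, c("_nodes.tsv", "_edges.tsv", "_signals.tsv"))
  }
}

read_network_tsv <- function(path) {
  p <- tsv_paths(path)
  if (!file.exists(p[1])) stop("nodes table not found: ", p[1])
  nodes <- utils::read.delim(p[1], stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  edges <- if (file.exists(p[2]))
    utils::read.delim(p[2], stringsAsFactors = FALSE, fileEncoding = "UTF-8") else NULL
  signals <- list()
  if (file.exists(p[3])) {
    s <- utils::read.delim(p[3], stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    signals <- as.list(stats::setNames(s$value, s$key))
  }
  regnet(nodes, edges, signals = signals)
}

read_network_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  bad <- lengths(parts) != 3
  if (any(bad)) stop("malformed SIF record: ", lines[bad][1])
  m <- do.call(rbind, parts)
  sign <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(sign) || !all(sign %in% c(-1L, 1L)))
    stop("SIF relation must be +1 or -1, got: ", m[is.na(sign) | !m[, 2] %in% c("1", "+1", "-1"), 2][1])
  ids <- unique(c(m[, 1], m[, 3]))
  regnet(data.frame(id = ids, stringsAsFactors = FALSE),
         data.frame(source = m[, 1], target = m[, 3], sign = sign,
                    stringsAsFactors = FALSE))
}

#' Write a regulatory network to disk
#'
#' `read_network(write_network(net, ...))` is the identity on nodes, edges,
#' modes and signal designations for the json and tsv dialects; sif export is
#' lossy (edges only) and provided for interoperability.
#'
#' @param net a `regnet`.
#' @param path destination file (json, sif) or directory/prefix (tsv).
#' @param format one of `"json"`, `"tsv"`, `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("json", "tsv", "sif")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "json") {
    doc <- list(name = net$name, nodes = net$nodes, edges = net$edges,
                signals = net$signals)
    doc <- doc[!vapply(doc, is.null, logical(1))]
    json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
    writeLines(json, path, useBytes = TRUE)
  } else if (format == "tsv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    p <- tsv_paths(path)
    utils::write.table(net$nodes, p[1], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.table(net$edges, p[2], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    if (length(net$signals)) {
      s <- data.frame(key = names(net$signals),
                      value = unlist(net$signals, use.names = FALSE),
                      stringsAsFactors = FALSE)
      utils::write.table(s, p[3], sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
    }
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(net$edges))
      writeLines(paste(net$edges$source, ifelse(net$edges$sign > 0, "+1", "-1"),
                       net$edges$target, sep = "\t"), con)
  }
  invisible(path)
}
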