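#' Gene-set collections and the GMT exchange format
#'
#' A `gene_set_collection` holds named member-gene vectors plus per-set
#' metadata (contributor, category code `C1..C7`, organism). The metadata
#' travel in the GMT description field as `key=value` pairs separated by
#' semicolons, so a collection round-trips through [write_gmt()] /
#' [read_gmt()] exactly.
#'
#' @param sets named list of character vectors (unique names, non-empty sets).
#' @param meta data frame with columns `name`, `contributor`, `category`,
#'   `organism`, one row per set (recycled defaults if omitted).
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, meta = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  if (any(!lengths(sets))) stop("gene sets must be non-empty")
  sets <- lapply(sets, as.character)
  if (is.null(meta)) {
    meta <- data.frame(name = names(sets),
                       contributor = rep(NA_character_, length(sets)),
                       category = rep(NA_character_, length(sets)),
                       organism = rep(NA_character_, length(sets)),
                       stringsAsFactors = FALSE)
  }
  stopifnot(identical(meta$name, names(sets)))
  structure(list(sets = sets, meta = meta), class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
`[.gene_set_collection` <- function(x, i) {
  keep <- if (is.character(i)) match(i, names(x$sets)) else i
  gene_set_collection(x$sets[keep], x$meta[keep, , drop = FALSE])
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene set collection: %d sets, sizes %s\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

parse_gmt_description_ <- function(desc) {
  out <- c(contributor = NA_character_, category = NA_character_,
           organism = NA_character_)
  for (field in strsplit(desc, "[;|]")[[1]]) {
    kv <- strsplit(field, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L && kv[1] %in% names(out)) out[[kv[1]]] <- trimws(kv[2])
  }
  out
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, member genes. The
#' description may carry `organism=...;category=...;contributor=...`
#' metadata, as written by [write_gmt()].
#'
#' @param path file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  meta <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected name, description and at least one gene", i))
    }
    sets[[fields[1]]] <- fields[-(1:2)]
    meta[[i]] <- parse_gmt_description_(fields[2])
  }
  meta <- as.data.frame(do.call(rbind, meta), stringsAsFactors = FALSE)
  if (!length(sets)) return(gene_set_collection(sets = structure(list(), names = character(0))))
  meta <- cbind(data.frame(name = names(sets), stringsAsFactors = FALSE), meta)
  gene_set_collection(sets, meta)
}

#' Write a gene-set collection as GMT
#'
#' @param coll a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  desc <- sprintf("organism=%s;category=%s;contributor=%s",
                  coll$meta$organism, coll$meta$category,
                  coll$meta$contributor)
  lines <- vapply(seq_along(coll$sets), function(i) {
    paste(c(names(coll$sets)[i], desc[i], coll$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
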