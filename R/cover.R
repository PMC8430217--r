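#' Construct a complex cover
#'
#' A `complex_cover` is an ordered collection of node-label sets.  Sets may
#' overlap and need not cover every node of a network; this is both the
#' detection output format and the reference-catalog format.
#'
#' @param complexes list of character vectors (each deduplicated to a set).
#' @param name free-text provenance tag.
#' @return An object of class `complex_cover`.
#' @export
complex_cover <- function(complexes, name = "") {
  complexes <- lapply(complexes, function(s) unique(as.character(s)))
  if (any(lengths(complexes) == 0L)) stop("complexes must be non-empty sets")
  structure(list(complexes = complexes, name = name), class = "complex_cover")
}

#' @method print complex_cover
#' @export
print.complex_cover <- function(x, ...) {
  sz <- lengths(x$complexes)
  cat(sprintf("<complex_cover>%s %d complexes, sizes %s\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(sz),
              if (length(sz)) paste0("[", min(sz), ", ", max(sz), "]") else "[]"))
  invisible(x)
}

#' @method length complex_cover
#' @export
length.complex_cover <- function(x) length(x$complexes)

#' Read a flat complex catalog
#'
#' One complex per line, whitespace/tab-separated protein IDs (the flat
#' format used by curated catalogs such as CORUM dumps).  Within-line
#' duplicate IDs are deduplicated with a warning; blank lines are skipped.
#'
#' @param path path to the catalog file.
#' @param name provenance tag stored on the cover (defaults to the filename).
#' @return A [complex_cover()].
#' @export
read_complexes <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no complexes in ", path)
  sets <- strsplit(lines, "[ \t]+")
  ndup <- sum(lengths(sets) - lengths(lapply(sets, unique)))
  if (ndup > 0) warning(ndup, " duplicate ID(s) within complexes deduplicated")
  complex_cover(lapply(sets, unique), name = name)
}

#' Write a complex cover to a flat catalog file
#'
#' One complex per line, tab-separated IDs; round-trips with
#' [read_complexes()].
#'
#' @param cover a `complex_cover`.
#' @param path output file path.
#' @export
write_cover <- function(cover, path) {
  writeLines(vapply(cover$complexes, paste, "", collapse = "\t"), path)
  invisible(NULL)
}

#' Restrict a cover to a network's node set
#'
#' Intersects every complex with the network's nodes and drops complexes
#' left with fewer than `min_size` members — the standard preprocessing of a
#' curated catalog against a specific interaction network (members absent
#' from the network are filtered out; only complexes with at least three
#' distinct surviving proteins are retained by default).
#'
#' @param cover a `complex_cover`.
#' @param net a `ppi_network`.
#' @param min_size minimum surviving size (default 3).
#' @return The restricted `complex_cover`, order preserved.
#' @export
restrict_cover <- function(cover, net, min_size = 3) {
  stopifnot(min_size >= 1)
  kept <- lapply(cover$complexes, intersect, net$nodes)
  kept <- kept[lengths(kept) >= min_size]
  structure(list(complexes = kept, name = cover$name), class = "complex_cover")
}

#' Drop complexes below a minimum size
#'
#' Predicted complexes with fewer than `min_size` members are removed
#' (default 3, the conventional smallest complex reported).
#'
#' @param cover a `complex_cover`.
#' @param min_size minimum retained size.
#' @return Filtered `complex_cover`, order preserved.
#' @export
filter_cover <- function(cover, min_size = 3) {
  stopifnot(min_size >= 1)
  structure(list(complexes = cover$complexes[lengths(cover$complexes) >= min_size],
                 name = cover$name), class = "complex_cover")
}

#' Remove exact duplicate complexes
#'
#' Distinct columns of a membership matrix can select identical member
#' sets; this keeps the first occurrence of each set (subset relations are
#' not duplicates and are kept).
#'
#' @param cover a `complex_cover`.
#' @return Deduplicated `complex_cover`.
#' @export
dedupe_cover <- function(cover) {
  keys <- vapply(cover$complexes, function(s) paste(sort(s), collapse = "\r"), "")
  dup <- duplicated(keys)
  if (any(dup)) message(sum(dup), " duplicate complex(es) removed")
  structure(list(complexes = cover$complexes[!dup], name = cover$name),
            class = "complex_cover")
}
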