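# ---- atom selections --------------------------------------------------------

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

#' Select atoms from a structure
#'
#' Predicates follow MD-analysis conventions: `"heavy"` selects all non-
#' hydrogen atoms, `"mainchain"` (alias `"backbone"`) the N, CA, C, O atoms,
#' `"all"` everything. A region (by name, against a region map) or an explicit
#' author-numbered residue range may further restrict the set. Selections are
#' deterministic and order-preserving.
#'
#' @param struct an `mdu_structure`.
#' @param what one of `"all"`, `"heavy"`, `"mainchain"`, `"backbone"`.
#' @param region optional region name, resolved against `regions`.
#' @param regions an `mdu_regions` map (required when `region` is given).
#' @param residues optional integer vector of author residue numbers to keep.
#' @return Integer vector of atom indices (attribute `what` records the
#'   predicate kind).
#' @export
select_atoms <- function(struct, what = c("all", "heavy", "mainchain", "backbone"),
                         region = NULL, regions = NULL, residues = NULL) {
  stopifnot(inherits(struct, "mdu_structure"))
  what <- match.arg(what)
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (what == "heavy") keep <- !(a$element %in% c("H", "D"))
  if (what %in% c("mainchain", "backbone"))
    keep <- a$name %in% MAINCHAIN_ATOMS & !(a$element %in% c("H", "D"))
  if (!is.null(region)) {
    if (is.null(regions)) stop("a region map must be supplied with `region`")
    rng <- region_range(regions, region)
    keep <- keep & a$resno >= rng[1] & a$resno <= rng[2]
  }
  if (!is.null(residues)) keep <- keep & a$resno %in% residues
  idx <- which(keep)
  attr(idx, "what") <- what
  idx
}

#' Residue composition of a structure
#'
#' Counts residues by 3-letter residue name; independent of the number of
#' models and of atom ordering within residues.
#'
#' @param struct an `mdu_structure`.
#' @return A list with `counts` (named integer vector, residue name -> count)
#'   and `total` (total residue count).
#' @export
residue_composition <- function(struct) {
  stopifnot(inherits(struct, "mdu_structure"))
  a <- struct$atoms
  if (nrow(a) == 0L) stop("structure has no residues")
  per_res <- a$resname[!duplicated(a$resid)]
  counts <- table(per_res)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       total = length(per_res))
}

# ---- region maps ------------------------------------------------------------

new_regions <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("name", "start", "end", "label")
  if (!all(need %in% names(df))) stop("region table needs columns: ",
                                      paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stop("region config error: duplicate region name(s): ",
                                   paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  if (any(df$start > df$end)) stop("region config error: start > end for region(s): ",
                                   paste(df$name[df$start > df$end], collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("mdu_regions", "data.frame"))
}

#' Built-in region map for human gammaD-crystallin
#'
#' Named residue ranges (author numbering, Met-inclusive: the mature chain
#' occupies positions 2..174) of the motifs, strands and domains used in
#' early-unfolding analyses of HGDC, e.g. the motif 2 beta3-strand G61~A64
#' that detaches first, its antiparallel partner motif 1 beta3-strand
#' C33~V38, and the aggregation-prone stretch L54~L58.
#'
#' @return An `mdu_regions` data frame (name, start, end, label).
#' @export
default_regions <- function() {
  new_regions(data.frame(
    name = c("motif2_beta3", "motif1_beta3", "motif2_beta2", "motif3_loop",
             "denovo_strand", "aggregation_stretch", "motif4_b2b3",
             "N_td", "C_td"),
    start = c(61, 33, 55, 109, 116, 54, 138, 2, 88),
    end   = c(64, 38, 58, 118, 119, 58, 162, 83, 174),
    label = c("motif 2 beta3-strand (G61~A64)",
              "motif 1 beta3-strand (C33~V38)",
              "motif 2 beta2-strand (Q55~L58)",
              "motif 3 loop (C109~F118)",
              "de novo strand-forming region (F116~N119)",
              "aggregation-prone stretch (L54~L58)",
              "motif 4 beta2/beta3 strands (N138~A162)",
              "N-terminal domain",
              "C-terminal domain"),
    stringsAsFactors = FALSE))
}

#' Load a region map from a key-value config file
#'
#' Config lines have the form `name = start-end` with an optional
#' `: label` suffix; blank lines and `#` comments are ignored. When `path`
#' is `NULL` and `defaults = TRUE`, the packaged HGDC map is returned.
#'
#' @param path path to a region config file, or `NULL`.
#' @param defaults include the built-in HGDC regions when no file is given.
#' @return An `mdu_regions` data frame.
#' @export
load_regions <- function(path = NULL, defaults = TRUE) {
  if (is.null(path)) {
    if (defaults) return(default_regions())
    return(new_regions(data.frame(name = character(), start = integer(),
                                  end = integer(), label = character(),
                                  stringsAsFactors = FALSE)))
  }
  if (!file.exists(path)) stop("region config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    if (defaults) return(default_regions())
    return(load_regions(NULL, defaults = FALSE))
  }
  parse_one <- function(ln) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("region config error: cannot parse line: ", ln)
    name <- trimws(kv[1])
    rhs <- trimws(gsub('"', "", kv[2]))
    lab <- ""
    if (grepl(":", rhs, fixed = TRUE)) {
      parts <- strsplit(rhs, ":", fixed = TRUE)[[1]]
      rhs <- trimws(parts[1]); lab <- trimws(paste(parts[-1], collapse = ":"))
    }
    se <- suppressWarnings(as.integer(strsplit(rhs, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2 || anyNA(se))
      stop("region config error: expected 'start-end' in line: ", ln)
    data.frame(name = name, start = se[1], end = se[2], label = lab,
               stringsAsFactors = FALSE)
  }
  new_regions(do.call(rbind, lapply(lines, parse_one)))
}

#' Look up a region's residue range
#'
#' @param regions an `mdu_regions` map.
#' @param name region name.
#' @return Integer vector `c(start, end)` in author numbering.
#' @export
region_range <- function(regions, name) {
  i <- match(name, regions$name)
  if (is.na(i)) stop("unknown region name: ", name)
  c(regions$start[i], regions$end[i])
}

# residues (sequential index) covered by a region, for a given topology
region_resids <- function(struct, regions, name) {
  rng <- region_range(regions, name)
  a <- struct$atoms
  sort(unique(a$resid[a$resno >= rng[1] & a$resno <= rng[2]]))
}

#' @export
print.mdu_regions <- function(x, ...) {
  cat(sprintf("<mdu_regions> %d region(s)\n", nrow(x)))
  print.data.frame(x)
  invisible(x)
}

#' Write a region map to a key-value config file
#'
#' @param regions an `mdu_regions` map.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  lines <- sprintf("%s = %d-%d%s", regions$name, regions$start, regions$end,
                   ifelse(nzchar(regions$label), paste0(" : ", regions$label), ""))
  writeLines(lines, path)
  invisible(path)
}
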