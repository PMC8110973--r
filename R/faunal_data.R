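#' Construct a validated occurrence matrix
#'
#' An occurrence matrix records the presence (1) or absence (0) of taxa
#' (rows) across faunas, i.e. fossil assemblages or localities (columns).
#' Column order carries meaning downstream: it is the working temporal
#' order of the faunas, oldest first.
#'
#' @param incidence numeric or integer matrix of 0/1 values, taxa in rows,
#'   faunas in columns. Dimnames are used as identifiers when `taxa` or
#'   `faunas` are not given.
#' @param taxa character vector of unique taxon identifiers.
#' @param faunas character vector of unique fauna identifiers, in working
#'   temporal order (oldest to youngest).
#' @param composite logical vector marking pseudo-fauna columns (boundary
#'   composites) that must be excluded from richness reporting. Recycled to
#'   `FALSE` when omitted.
#'
#' @return An object of class `occurrence_matrix`: an integer 0/1 matrix with
#'   taxon rownames, fauna colnames and a `composite` attribute.
#' @examples
#' m <- occurrence_matrix(rbind(t1 = c(1, 0), t2 = c(1, 1), t3 = c(0, 1)),
#'                        faunas = c("A", "B"))
#' dim(m)
#' @export
occurrence_matrix <- function(incidence, taxa = rownames(incidence),
                              faunas = colnames(incidence),
                              composite = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(taxa) || is.null(faunas))
    stop("taxon and fauna identifiers are required (dimnames or arguments)")
  taxa <- as.character(taxa)
  faunas <- as.character(faunas)
  if (length(taxa) != nrow(incidence) || length(faunas) != ncol(incidence))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(faunas))
    stop("duplicate fauna identifiers: ",
         paste(unique(faunas[duplicated(faunas)]), collapse = ", "))
  bad <- which(!(incidence %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(incidence)) + 1
    j <- ((bad[1] - 1) %/% nrow(incidence)) + 1
    stop(sprintf("non-binary cell at taxon '%s', fauna '%s': %s",
                 taxa[i], faunas[j], format(incidence[i, j])))
  }
  storage.mode(incidence) <- "integer"
  empty <- rowSums(incidence) == 0
  if (any(empty))
    stop("taxa with no occurrences: ",
         paste(taxa[empty], collapse = ", "))
  if (is.null(composite)) composite <- rep(FALSE, length(faunas))
  if (length(composite) != length(faunas))
    stop("composite flag length must equal number of faunas")
  dimnames(incidence) <- list(taxa, faunas)
  structure(incidence, composite = as.logical(composite),
            class = c("occurrence_matrix", "matrix", "array"))
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d taxa x %d faunas (%d presences)\n",
              nrow(x), ncol(x), sum(x)))
  if (any(attr(x, "composite")))
    cat("  composite faunas:",
        paste(colnames(x)[attr(x, "composite")], collapse = ", "), "\n")
  cat("  faunas (oldest first):", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

taxa_of <- function(m) rownames(m)
faunas_of <- function(m) colnames(m)
composite_of <- function(m) {
  cp <- attr(m, "composite")
  if (is.null(cp)) rep(FALSE, ncol(m)) else cp
}

# rebuild an occurrence_matrix keeping the composite flag aligned to columns
reclass_om <- function(incidence, composite = NULL) {
  occurrence_matrix(incidence, composite = composite)
}

#' Read an occurrence table from a delimited text file
#'
#' Expects a rectangular table whose first column holds taxon identifiers and
#' whose header row holds fauna identifiers, with 0/1 cells. The field
#' separator (comma or tab) is sniffed from the header line.
#'
#' @param path path to a UTF-8 CSV/TSV file.
#' @return An [occurrence_matrix()].
#' @export
read_occurrence_table <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("occurrence table needs a taxon column and >=1 fauna")
  taxa <- as.character(df[[1]])
  cells <- as.matrix(df[, -1, drop = FALSE])
  faunas <- colnames(cells)
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(num)) + 1
    j <- ((bad[1] - 1) %/% nrow(num)) + 1
    stop(sprintf("non-binary cell in row '%s', column '%s': '%s'",
                 taxa[i], faunas[j], cells[i, j]))
  }
  dimnames(num) <- list(taxa, faunas)
  occurrence_matrix(num)
}

#' Write an occurrence matrix as CSV
#' @param m an [occurrence_matrix()].
#' @param path output file path.
#' @export
write_occurrence_table <- function(m, path) {
  df <- data.frame(taxon = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read fauna metadata
#'
#' Columns recognised: `fauna`, `latitude`, `longitude`, `age_point`,
#' `age_min`, `age_max`, `section`, `region`. Ages are Ma before present
#' (larger = older); `age_max` is the older bound and `age_min` the younger,
#' so `age_max >= age_point >= age_min` where all are present. `section`
#' groups faunas from the same stratigraphic formation; within a section the
#' file order is stratigraphic (oldest first).
#'
#' @param path delimited text file (separator sniffed).
#' @return data.frame of class `fauna_metadata`.
#' @export
read_fauna_metadata <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  fauna_metadata(df)
}

#' Validate a fauna metadata table
#' @param df data.frame with at least a `fauna` column; see
#'   [read_fauna_metadata()] for recognised columns.
#' @return the validated data.frame, classed `fauna_metadata`.
#' @export
fauna_metadata <- function(df) {
  if (!"fauna" %in% names(df)) stop("metadata must have a 'fauna' column")
  df$fauna <- as.character(df$fauna)
  if (anyDuplicated(df$fauna))
    stop("duplicate fauna identifiers in metadata")
  for (col in c("latitude", "longitude", "age_point", "age_min", "age_max"))
    if (!col %in% names(df)) df[[col]] <- NA_real_ else
      df[[col]] <- as.numeric(df[[col]])
  if (!"section" %in% names(df)) df$section <- NA_character_
  if (!"region" %in% names(df)) df$region <- NA_character_
  if (any(!is.na(df$latitude) & abs(df$latitude) > 90))
    stop("latitude outside [-90, 90]")
  if (any(!is.na(df$longitude) & abs(df$longitude) > 180))
    stop("longitude outside [-180, 180]")
  ok <- function(hi, lo) is.na(hi) | is.na(lo) | hi >= lo
  if (!all(ok(df$age_max, df$age_point)) || !all(ok(df$age_point, df$age_min)) ||
      !all(ok(df$age_max, df$age_min)))
    stop("age bounds must satisfy age_max >= age_point >= age_min (Ma)")
  class(df) <- c("fauna_metadata", "data.frame")
  df
}

#' Fixed trait vocabularies
#'
#' The eleven analysed mammalian groups, five dietary classes and seven body
#' size classes (I, < 100 g; II, 100 g - 1 kg; III, 1-10 kg; IV, 10-100 kg;
#' V, 100-500 kg; VI, 500-1000 kg; VII, > 1000 kg).
#' @name trait_vocabularies
#' @export
taxonomic_groups <- c("Sparassodonta", "Marsupialia", "Cingulata", "Pilosa",
                      "Notoungulata", "Litopterna", "Caviomorpha", "Cricetidae",
                      "Perissodactyla", "Artiodactyla", "Carnivora")

#' @rdname trait_vocabularies
#' @export
diet_classes <- c("carnivorous", "generalist", "grazer", "mixed feeder",
                  "browser")

#' @rdname trait_vocabularies
#' @export
body_size_classes <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Read or validate per-taxon trait labels
#'
#' Columns: `taxon`, `group`, `diet`, `size`. Labels must come from the fixed
#' vocabularies ([taxonomic_groups], [diet_classes], [body_size_classes]);
#' missing labels are allowed (`NA`) and are excluded, with a logged count,
#' from community-structure analyses.
#'
#' @param path delimited text file.
#' @return data.frame of class `taxon_traits`.
#' @export
read_taxon_traits <- function(path) {
  sep <- sniff_sep(path)
  taxon_traits(utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname read_taxon_traits
#' @param df data.frame with columns `taxon`, `group`, `diet`, `size`.
#' @export
taxon_traits <- function(df) {
  if (!"taxon" %in% names(df)) stop("traits must have a 'taxon' column")
  df$taxon <- as.character(df$taxon)
  if (anyDuplicated(df$taxon)) stop("duplicate taxon identifiers in traits")
  for (col in c("group", "diet", "size"))
    if (!col %in% names(df)) df[[col]] <- NA_character_ else
      df[[col]] <- as.character(df[[col]])
  chk <- function(x, vocab, what) {
    bad <- !is.na(x) & !(x %in% vocab)
    if (any(bad))
      stop(sprintf("unknown %s label(s): %s", what,
                   paste(unique(x[bad]), collapse = ", ")))
  }
  chk(df$group, taxonomic_groups, "taxonomic group")
  chk(df$diet, diet_classes, "diet")
  chk(df$size, body_size_classes, "body size")
  class(df) <- c("taxon_traits", "data.frame")
  df
}

#' Remove single-fauna taxa
#'
#' Taxa occurring in exactly one fauna carry no seriation signal and are
#' excluded before ordination and appearance event ordination.
#'
#' @param m an [occurrence_matrix()].
#' @return the matrix without singleton taxa; the fauna set is unchanged.
#' @export
drop_singletons <- function(m) {
  keep <- rowSums(m) > 1L
  if (!any(keep))
    stop("all taxa are singletons; nothing left after removal")
  reclass_om(unclass(m)[keep, , drop = FALSE], composite_of(m))
}

#' Fill Lazarus gaps by range-through interpolation
#'
#' A Lazarus taxon is absent from an intermediate level but present in
#' earlier and later levels; under the range-through convention it is scored
#' present at every fauna strictly between its first and last occurrence in
#' the supplied temporal order.
#'
#' @param m an [occurrence_matrix()].
#' @param order character vector of fauna identifiers, oldest first; must
#'   contain every fauna of `m`. Defaults to the matrix column order.
#' @return an [occurrence_matrix()] whose presences are a superset of the
#'   input's. Idempotent.
#' @export
range_through_fill <- function(m, order = faunas_of(m)) {
  order <- as.character(order)
  if (!setequal(order, faunas_of(m)) || length(order) != ncol(m))
    stop("'order' must be a permutation of the matrix faunas")
  pos <- match(order, faunas_of(m))
  inc <- unclass(m)[, pos, drop = FALSE]
  for (i in seq_len(nrow(inc))) {
    occ <- which(inc[i, ] == 1L)
    if (length(occ) > 1L) inc[i, occ[1L]:occ[length(occ)]] <- 1L
  }
  # restore original column order
  inc <- inc[, match(faunas_of(m), colnames(inc)), drop = FALSE]
  reclass_om(inc, composite_of(m))
}

#' Merge faunas pairwise (or in larger groups)
#'
#' Used to pool assemblages judged to represent the same fauna. The merged
#' column is the elementwise OR of the member columns and replaces the
#' members at the position of the first member in the fauna order.
#'
#' @param m an [occurrence_matrix()].
#' @param groups named list; each element a character vector of >=2 fauna
#'   identifiers to merge, the element name giving the merged identifier
#'   (unnamed elements are named by joining member ids with "+").
#' @return an [occurrence_matrix()] with merged columns.
#' @export
merge_faunas <- function(m, groups) {
  stopifnot(is.list(groups), length(groups) > 0)
  nm <- names(groups)
  if (is.null(nm)) nm <- rep("", length(groups))
  all_members <- unlist(groups)
  unknown <- setdiff(all_members, faunas_of(m))
  if (length(unknown))
    stop("unknown fauna id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(all_members))
    stop("a fauna may belong to at most one merge group")
  if (any(lengths(groups) < 2)) stop("each merge group needs >= 2 faunas")
  inc <- unclass(m)
  comp <- composite_of(m)
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    label <- if (nzchar(nm[k])) nm[k] else paste(g, collapse = "+")
    j <- match(g, colnames(inc))
    merged <- as.integer(rowSums(inc[, j, drop = FALSE]) > 0)
    inc[, j[1L]] <- merged
    colnames(inc)[j[1L]] <- label
    comp[j[1L]] <- any(comp[j])
    inc <- inc[, -j[-1L], drop = FALSE]
    comp <- comp[-j[-1L]]
  }
  keep <- rowSums(inc) > 0
  reclass_om(inc[keep, , drop = FALSE], comp)
}

#' Merge fauna metadata consistently with [merge_faunas()]
#'
#' The merged age point is the midpoint of the member age midpoints (each
#' member's midpoint being its `age_point` or, failing that, the mean of its
#' bounds); merged bounds span the members; coordinates are averaged.
#'
#' @param meta a [fauna_metadata()] table.
#' @param groups as in [merge_faunas()].
#' @return merged `fauna_metadata`.
#' @export
merge_fauna_metadata <- function(meta, groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- rep("", length(groups))
  out <- meta
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    label <- if (nzchar(nm[k])) nm[k] else paste(g, collapse = "+")
    i <- match(g, out$fauna)
    if (anyNA(i)) stop("unknown fauna id(s) in metadata merge")
    mids <- ifelse(is.na(out$age_point[i]),
                   (out$age_max[i] + out$age_min[i]) / 2, out$age_point[i])
    row <- out[i[1L], ]
    row$fauna <- label
    row$age_point <- if (all(is.na(mids))) NA_real_ else mean(mids, na.rm = TRUE)
    row$age_max <- if (all(is.na(out$age_max[i]))) NA_real_ else
      max(out$age_max[i], na.rm = TRUE)
    row$age_min <- if (all(is.na(out$age_min[i]))) NA_real_ else
      min(out$age_min[i], na.rm = TRUE)
    row$latitude <- mean(out$latitude[i], na.rm = TRUE)
    row$longitude <- mean(out$longitude[i], na.rm = TRUE)
    secs <- unique(stats::na.omit(out$section[i]))
    row$section <- if (length(secs) == 1) secs else NA_character_
    out[i[1L], ] <- row
    out <- out[-i[-1L], , drop = FALSE]
  }
  rownames(out) <- NULL
  fauna_metadata(out)
}

#' Append boundary composite pseudo-faunas
#'
#' To permit boundary-crosser counts at the sequence edges, an "older"
#' composite (taxa shared with assemblages predating the sequence) is
#' prepended and a "younger" composite (taxa shared with assemblages
#' postdating it) appended. Composite columns are flagged and excluded from
#' richness reporting.
#'
#' @param m an [occurrence_matrix()].
#' @param older_taxa,younger_taxa character vectors of taxa (subsets of the
#'   matrix taxa) present in the older/younger composite.
#' @param names identifiers for the two pseudo-faunas.
#' @return an [occurrence_matrix()] with two flagged composite columns.
#' @export
add_boundary_composites <- function(m, older_taxa = character(),
                                    younger_taxa = character(),
                                    names = c("OLDER", "YOUNGER")) {
  unknown <- setdiff(c(older_taxa, younger_taxa), taxa_of(m))
  if (length(unknown))
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "))
  inc <- unclass(m)
  old_col <- as.integer(rownames(inc) %in% older_taxa)
  yng_col <- as.integer(rownames(inc) %in% younger_taxa)
  out <- cbind(old_col, inc, yng_col)
  colnames(out) <- c(names[1L], colnames(inc), names[2L])
  comp <- c(TRUE, composite_of(m), TRUE)
  # occurrence_matrix() rejects empty taxa; composites may not rescue any
  reclass_om(out, comp)
}

#' Export the matrix as a NEXUS or TNT character block
#'
#' Faunas become terminals and taxa binary characters, the layout used for
#' parsimony analysis of endemicity. Identifiers are sanitised (whitespace
#' and dialect-illegal characters replaced by "_"); the mapping is attached
#' as the `sanitized` attribute when any name changes.
#'
#' @param m an [occurrence_matrix()].
#' @param dialect `"nexus"` or `"tnt"`.
#' @return a character scalar with the matrix in the requested dialect.
#' @export
export_character_matrix <- function(m, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  X <- t(unclass(m)) # faunas x taxa
  labels <- sanitize_labels(rownames(X))
  chars <- sanitize_labels(colnames(X))
  rows <- apply(X, 1, paste, collapse = "")
  body <- paste(sprintf("%s  %s", labels$clean, rows), collapse = "\n")
  txt <- if (dialect == "nexus") {
    paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=", nrow(X),
           " NCHAR=", ncol(X), ";\n",
           "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;\n",
           "CHARLABELS ", paste(chars$clean, collapse = " "), ";\nMATRIX\n",
           body, "\n;\nEND;\n")
  } else {
    paste0("xread\n'faunas as terminals, taxa as binary characters'\n",
           ncol(X), " ", nrow(X), "\n", body, "\n;\n")
  }
  if (any(labels$clean != labels$raw))
    attr(txt, "sanitized") <- stats::setNames(labels$clean, labels$raw)
  txt
}

sanitize_labels <- function(x) {
  clean <- gsub("[^A-Za-z0-9_.]", "_", x)
  clean <- make.unique(clean, sep = "_")
  list(raw = x, clean = clean)
}

#' Write/read character matrices for external parsimony programs
#'
#' `read_character_matrix()` round-trips the output of
#' [export_character_matrix()]: it returns an [occurrence_matrix()] with
#' faunas as columns again.
#'
#' @param m an [occurrence_matrix()].
#' @param path file path.
#' @inheritParams export_character_matrix
#' @export
write_character_matrix <- function(m, path, dialect = c("nexus", "tnt")) {
  txt <- export_character_matrix(m, dialect)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

#' @rdname write_character_matrix
#' @export
read_character_matrix <- function(path, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "nexus") {
    start <- grep("^MATRIX$", toupper(trimws(lines)))[1] + 1L
  } else {
    # xread: title line, dims line, then matrix rows
    dims <- grep("^[0-9]+ +[0-9]+$", trimws(lines))[1]
    start <- dims + 1L
  }
  end <- grep("^;", trimws(lines))
  end <- end[end >= start][1] - 1L
  rows <- trimws(lines[start:end])
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "[ \t]+")
  labs <- vapply(parts, `[[`, "", 1L)
  states <- vapply(parts, function(p) p[[length(p)]], "")
  X <- do.call(rbind, lapply(strsplit(states, ""), as.integer))
  rownames(X) <- labs
  cl <- grep("^CHARLABELS ", trimws(lines), value = TRUE)
  colnames(X) <- if (length(cl)) {
    strsplit(sub(";\\s*$", "", sub("^CHARLABELS ", "", trimws(cl[1]))),
             " +")[[1]]
  } else paste0("char", seq_len(ncol(X)))
  occurrence_matrix(t(X))
}

#' Duplicate genus-level entries
#'
#' Optionally expands the matrix with genus-level rows (the OR over species
#' of the same genus, genus taken as the first whitespace-delimited token of
#' the taxon name) where a genus has two or more species entries. Off by
#' default in all analyses.
#'
#' @param m an [occurrence_matrix()].
#' @param sep regular expression splitting the genus token from the name.
#' @return an [occurrence_matrix()] with extra `<Genus> (genus)` rows.
#' @export
expand_genus_entries <- function(m, sep = "[ _]") {
  genus <- vapply(strsplit(taxa_of(m), sep), `[[`, "", 1L)
  dup <- names(which(table(genus) >= 2))
  if (!length(dup)) return(m)
  extra <- t(vapply(dup, function(g) {
    as.integer(colSums(unclass(m)[genus == g, , drop = FALSE]) > 0)
  }, integer(ncol(m))))
  rownames(extra) <- paste0(dup, " (genus)")
  reclass_om(rbind(unclass(m), extra), composite_of(m))
}

#' Cross-validate occurrence data, metadata and traits
#'
#' @param m an [occurrence_matrix()].
#' @param metadata optional [fauna_metadata()].
#' @param traits optional [taxon_traits()].
#' @return character vector of findings (empty when fully consistent),
#'   invisibly; findings are also messaged.
#' @export
validate_faunal_data <- function(m, metadata = NULL, traits = NULL) {
  notes <- character()
  if (!is.null(metadata)) {
    miss <- setdiff(faunas_of(m)[!composite_of(m)], metadata$fauna)
    if (length(miss))
      notes <- c(notes, paste("faunas without metadata:",
                              paste(miss, collapse = ", ")))
  }
  if (!is.null(traits)) {
    miss <- setdiff(taxa_of(m), traits$taxon)
    if (length(miss))
      notes <- c(notes, sprintf("%d taxa without trait labels", length(miss)))
  }
  for (n in notes) message(n)
  invisible(notes)
}
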