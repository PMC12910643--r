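# Multi-conformer structure I/O: multi-model PDB and multi-frame XYZ.
# No coordinate transformation is applied on read; frames keep file order.

#' Read a multi-conformer structure file
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL` records, element
#' taken from columns 77-78) and multi-frame XYZ (count line, comment line,
#' `element x y z` rows, repeated). All models must have identical atom
#' count and ordering; a mismatch is a parse error naming the offending
#' model.
#'
#' @param path File path.
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension.
#' @param environment Environment label stored on the ensemble.
#' @return A [conformer_ensemble] (topology not yet annotated; see
#'   [annotate_ensemble()]).
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"),
                          environment = "unlabelled") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", ent = "pdb", xyz = "xyz",
                     abort("cannot guess format from extension; pass `format`"))
  }
  lines <- readLines(path, warn = FALSE)
  parsed <- if (format == "pdb") parse_pdb_models(lines) else
    parse_xyz_frames(lines)
  ref <- parsed[[1]]
  for (m in seq_along(parsed)) {
    if (nrow(parsed[[m]]) != nrow(ref))
      abort(sprintf(
        "MODEL %d has %d atoms; MODEL 1 has %d (atom count must match)",
        m, nrow(parsed[[m]]), nrow(ref)),
        class = "chameleonics_parse_error")
    if (!identical(parsed[[m]]$element, ref$element))
      abort(sprintf("MODEL %d atom ordering differs from MODEL 1", m),
            class = "chameleonics_parse_error")
  }
  element_properties(unique(ref$element))  # errors on unknown symbols
  frames <- lapply(parsed, function(df)
    unname(as.matrix(df[c("x", "y", "z")])))
  conformer_ensemble(
    frames, tibble(element = ref$element, name = ref$name),
    environment = environment, source = path)
}

parse_pdb_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  blocks <- if (length(model_starts) == 0) {
    list(which(is_atom))
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    purrr::map2(model_starts, ends, function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    })
  }
  blocks <- Filter(function(ix) length(ix) > 0, blocks)
  if (length(blocks) == 0) abort("no ATOM/HETATM records found",
                                 class = "chameleonics_parse_error")
  lapply(blocks, function(ix) {
    ln <- lines[ix]
    name <- trimws(substr(ln, 13, 16))
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    el <- trimws(substr(ln, 77, 78))
    # normalise element case ("CL" -> "Cl"); fall back to atom-name letter
    el <- ifelse(nchar(el) == 2,
                 paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))), el)
    miss <- el == ""
    el[miss] <- substr(gsub("[^A-Za-z].*", "", name[miss]), 1, 1)
    if (anyNA(c(x, y, z)))
      abort("unparseable coordinate field in ATOM record",
            class = "chameleonics_parse_error")
    tibble(element = el, name = name, x = x, y = y, z = z)
  })
}

parse_xyz_frames <- function(lines) {
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     seq_along(lines) == length(lines))]  # drop trailing blank
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      abort(sprintf("XYZ frame %d: bad atom-count line '%s'",
                    length(out) + 1L, lines[i]),
            class = "chameleonics_parse_error")
    if (i + 1L + n > length(lines))
      abort(sprintf("XYZ frame %d: truncated (expected %d atom lines)",
                    length(out) + 1L, n),
            class = "chameleonics_parse_error")
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(rows, length, 1L) < 4)
    if (length(bad) > 0)
      abort(sprintf("XYZ frame %d: malformed atom line %d",
                    length(out) + 1L, bad[1]),
            class = "chameleonics_parse_error")
    el <- vapply(rows, `[[`, "", 1)
    xyz <- vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))
    if (anyNA(xyz))
      abort(sprintf("XYZ frame %d: non-numeric coordinate",
                    length(out) + 1L),
            class = "chameleonics_parse_error")
    out[[length(out) + 1L]] <-
      tibble(element = el, name = el,
             x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
    i <- i + 2L + n
  }
  if (length(out) == 0) abort("empty XYZ file",
                              class = "chameleonics_parse_error")
  out
}

#' Write a conformer ensemble to disk
#'
#' Inverse of [read_ensemble()] up to format precision (PDB coordinates are
#' written with 3 decimals, XYZ with 6).
#'
#' @param ensemble A [conformer_ensemble].
#' @param path Output file path.
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension.
#' @param frames Optional integer vector restricting which frames to write.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("auto", "pdb", "xyz"),
                           frames = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", xyz = "xyz",
                     abort("cannot guess format from extension; pass `format`"))
  }
  keep <- frames %||% seq_len(n_frames(ensemble))
  if (length(keep) == 0) abort("no frames selected for writing")
  at <- ensemble$topology$atoms
  lines <- character()
  if (format == "pdb") {
    for (m in seq_along(keep)) {
      fr <- ensemble$frames[[keep[m]]]
      lines <- c(lines, sprintf("MODEL     %4d", m),
        sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                at$index, substr(at$name, 1, 4), "LIG", 1L,
                fr[, 1], fr[, 2], fr[, 3], 1, 0, toupper(at$element)),
        "ENDMDL")
    }
    lines <- c(lines, "END")
  } else {
    for (m in seq_along(keep)) {
      fr <- ensemble$frames[[keep[m]]]
      lines <- c(lines, as.character(nrow(at)),
                 sprintf("frame %d environment=%s", m, ensemble$environment),
                 sprintf("%-2s %14.6f %14.6f %14.6f",
                         at$element, fr[, 1], fr[, 2], fr[, 3]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
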