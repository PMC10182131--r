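.REQUIRED_COLS <- c("gene", "protein_change", "classification",
                    "ddg_fold", "cadd")
.NUMERIC_COLS <- c("pos", "ddg_fold", "cadd", "maf", "confidence",
                   "sasa_pct")

#' Read a variant table from TSV
#'
#' Reads a tab-separated variant table with a header line. Required columns:
#' \code{gene}, \code{protein_change}, \code{classification},
#' \code{ddg_fold}, \code{cadd}; recognized optional columns: \code{chrom},
#' \code{pos}, \code{ref}, \code{alt}, \code{maf}, \code{confidence},
#' \code{sasa_pct}, \code{in_domain}, \code{genome_build} (coordinates are
#' 1-based GRCh37 unless \code{genome_build} says otherwise). Empty fields
#' become \code{NA}; a malformed numeric field raises an error naming the
#' offending file line.
#'
#' @param path file path.
#' @return typed data.frame, one row per variant.
#' @seealso [writeVariantTable()] for the exact inverse.
#' @export
readVariantTable <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = "", check.names = FALSE)
  miss <- setdiff(.REQUIRED_COLS, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(raw$classification), c(.CLASS_LEVELS, NA))
  if (length(bad))
    stop("unknown classification label(s): ", paste(bad, collapse = ", "))
  for (col in intersect(.NUMERIC_COLS, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    badRow <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(badRow))
      stop(sprintf("malformed numeric in column '%s' at line %d: '%s'",
                   col, badRow[1] + 1L, raw[[col]][badRow[1]]))
    raw[[col]] <- if (col == "pos") as.integer(v) else v
  }
  if ("in_domain" %in% names(raw)) {
    v <- toupper(raw$in_domain)
    badRow <- which(!v %in% c("TRUE", "FALSE") & !is.na(v))
    if (length(badRow))
      stop(sprintf("malformed logical in column 'in_domain' at line %d",
                   badRow[1] + 1L))
    raw$in_domain <- as.logical(v)
  }
  raw
}

#' Write a variant table as TSV
#'
#' The inverse of [readVariantTable()]: tab-separated, UTF-8, LF line
#' endings, missing values as empty fields, numeric columns printed with
#' full (17 significant digit) precision so that a write/read round trip
#' reproduces every typed field exactly.
#'
#' @param variants variant data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  out <- variants
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein model from PDB
#'
#' Parses a fixed-column PDB file (first model only; alternate locations
#' restricted to blank or 'A'), assigns van der Waals radii from a fixed
#' element table (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Angstrom), and reads
#' per-residue model confidence from the B-factor column (the convention of
#' predicted structures: identical within a residue). Residue numbers are
#' remapped to a contiguous 1-based index in order of appearance, the
#' coordinate system all feature operators use.
#'
#' @param path PDB file path.
#' @return a [ProteinModel-class].
#' @seealso [writeProteinModel()], [sasaPerResidue()], [clashScore()]
#' @export
readProteinModel <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), ,
           drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele)) || all(ele == ""))
    ele <- bio3d::atom2ele(at$elety)
  ele <- toupper(trimws(ele))
  unknown <- setdiff(unique(ele), names(.VDW_RADII))
  if (length(unknown))
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  resIdx <- match(key, unique(key))
  conf <- at$b[!duplicated(resIdx)]
  if (any(is.na(conf) | conf < 0 | conf > 100))
    stop("B-factor column is not a confidence score in [0, 100]")
  atoms <- data.frame(element = ele, radius = unname(.VDW_RADII[ele]),
                      x = at$x, y = at$y, z = at$z, resno = resIdx,
                      resid = at$resid, name = at$elety,
                      stringsAsFactors = FALSE)
  new("ProteinModel", atoms = atoms,
      confidence = setNames(conf, as.character(unique(resIdx))))
}

#' Write a protein model as PDB
#'
#' Writes fixed-column PDB with the per-residue confidence score repeated in
#' the B-factor column of every atom of the residue (two decimal places),
#' residue numbering 1-based.
#'
#' @param model a [ProteinModel-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProteinModel <- function(model, path) {
  stopifnot(is(model, "ProteinModel"))
  at <- model@atoms
  conf <- model@confidence[as.character(at$resno)]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   chain = "A", o = rep(1, nrow(at)), b = unname(conf))
  invisible(path)
}

#' Read a domain annotation track from BED
#'
#' BED-style annotation on protein residue coordinates: tab-separated
#' columns protein id, start, end (0-based, half-open) and an optional name,
#' no header. Intervals are merged into a normalized [DomainTrack-class].
#'
#' @param path BED file path.
#' @param id optional protein id; when given, only intervals of that id are
#'   kept.
#' @return a [DomainTrack-class].
#' @export
readDomainBed <- function(path, id = NULL) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns")
  if (!is.null(id)) bed <- bed[bed[[1]] == id, , drop = FALSE]
  domainTrack(as.numeric(bed[[2]]), as.numeric(bed[[3]]))
}
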