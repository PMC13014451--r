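# Labeled coordinate frames of membrane snapshots. Component labels follow
# the membrane-system vocabulary: water (WAT), phospholipid headgroups
# (PC/PE/PS/PG), oleoyl tails (OL), cholesterol (CHL), the permeant drug
# (DRG) and monoatomic ions (ION).

.component_labels <- c("WAT", "PC", "PE", "PS", "PG", "OL", "CHL", "DRG", "ION")

# residue-name -> component label map for PDB input
.pdb_label_map <- c(
  HOH = "WAT", WAT = "WAT", TIP3 = "WAT", SPC = "WAT", SOL = "WAT",
  PC = "PC", POPC = "PC", PE = "PE", POPE = "PE", PS = "PS", POPS = "PS",
  PG = "PG", POPG = "PG", OL = "OL", CHL = "CHL", CLR = "CHL",
  DRG = "DRG", LIG = "DRG",
  "NA" = "ION", CL = "ION", K = "ION", MG = "ION", ION = "ION"
)

.electron_counts <- c(H = 1, C = 6, N = 7, O = 8, Na = 11, Mg = 12,
                      P = 15, S = 16, Cl = 17, K = 19, Pt = 78)

#' Labeled atomic frame
#'
#' A snapshot of a (toy) membrane system: element symbols, component labels
#' from the closed vocabulary WAT/PC/PE/PS/PG/OL/CHL/DRG/ION, Cartesian
#' coordinates in Angstrom, and optional per-atom charge (e) and radius (A).
#'
#' @param element character vector of element symbols.
#' @param label character vector of component labels.
#' @param x,y,z numeric coordinates (Angstrom), finite.
#' @param charge optional charges (e).
#' @param radius optional radii (Angstrom).
#' @param box optional orthorhombic box lengths, numeric length 3 (Angstrom).
#' @return a data.frame of class `mem_frame` with attribute `box`.
#' @export
mem_frame <- function(element, label, x, y, z, charge = NULL, radius = NULL,
                      box = NULL) {
  n <- length(element)
  if (any(lengths(list(label, x, y, z)) != n)) stop("field length mismatch")
  bad <- setdiff(unique(label), .component_labels)
  if (length(bad)) stop("unknown component label(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(x) & is.finite(y) & is.finite(z))) {
    stop("coordinates must be finite")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths")
    }
  }
  d <- data.frame(element = as.character(element), label = as.character(label),
                  x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                  stringsAsFactors = FALSE)
  if (!is.null(charge)) d$charge <- as.numeric(charge)
  if (!is.null(radius)) d$radius <- as.numeric(radius)
  attr(d, "box") <- box
  class(d) <- c("mem_frame", "data.frame")
  d
}

frame_box <- function(frame) attr(frame, "box")

#' Read labeled frames from extended XYZ or PDB
#'
#' The XYZ dialect is extended XYZ whose per-atom line carries a fifth
#' column with the component label (and optionally sixth/seventh columns
#' with charge and radius). PDB reading goes through `bio3d`; residue names
#' map onto component labels via a fixed table (HOH/WAT to WAT, CHL/CLR to
#' CHL, ...). Unknown residue names are accepted as ION only when the
#' residue is a single atom; otherwise reading aborts.
#'
#' @param path input file.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @return list of [mem_frame] objects in file order.
#' @export
read_frames <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop("frames file not found: ", path)
  if (format == "xyz") .read_frames_xyz(path) else .read_frames_pdb(path)
}

.read_frames_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    comment <- lines[i + 1L]
    box <- NULL
    bm <- regmatches(comment,
                     regexec("box=([0-9.eE+-]+)[ ,]([0-9.eE+-]+)[ ,]([0-9.eE+-]+)", comment))[[1]]
    if (length(bm) == 4L) box <- as.numeric(bm[2:4])
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[[:space:]]+")
    nf <- lengths(rec)
    if (any(nf < 5L)) {
      stop("malformed XYZ atom record at line ", i + 1L + which(nf < 5L)[1])
    }
    el <- vapply(rec, `[[`, "", 1L)
    xyz <- suppressWarnings(
      vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("non-numeric coordinate near line ", i + 2L)
    }
    lab <- vapply(rec, `[[`, "", 5L)
    charge <- if (all(nf >= 6L)) vapply(rec, function(r) as.numeric(r[6L]), 0) else NULL
    radius <- if (all(nf >= 7L)) vapply(rec, function(r) as.numeric(r[7L]), 0) else NULL
    frames[[length(frames) + 1L]] <-
      mem_frame(el, lab, xyz[1, ], xyz[2, ], xyz[3, ],
                charge = charge, radius = radius, box = box)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

.read_frames_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resid <- toupper(trimws(at$resid))
  lab <- unname(.pdb_label_map[resid])
  if (anyNA(lab)) {
    unknown <- unique(resid[is.na(lab)])
    for (u in unknown) {
      # unknown residues pass as ION only if monoatomic
      per_res <- table(paste(at$resid, at$resno)[resid == u])
      if (any(per_res > 1L)) {
        stop("unknown multi-atom residue in PDB: ", u)
      }
    }
    lab[is.na(lab)] <- "ION"
  }
  el <- trimws(at$elesy)
  if (any(!nzchar(el))) el <- substr(trimws(at$elety), 1, 1)
  nmodel <- nrow(pdb$xyz)
  lapply(seq_len(nmodel), function(m) {
    co <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    mem_frame(el, lab, co[, 1], co[, 2], co[, 3])
  })
}

#' Write labeled frames as extended XYZ
#'
#' One block per frame: atom count, a comment line (carrying `box=a,b,c`
#' when a box is present), then `element x y z label [charge [radius]]`
#' records at 1e-3 Angstrom precision or better.
#'
#' @param frames list of [mem_frame] objects.
#' @param path output file.
#' @param digits coordinate digits after the decimal point (default 6).
#' @export
write_frames_xyz <- function(frames, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df %%s", digits, digits, digits)
  for (fr in frames) {
    writeLines(as.character(nrow(fr)), con)
    box <- frame_box(fr)
    writeLines(if (is.null(box)) "frame" else
               sprintf("frame box=%.6f,%.6f,%.6f", box[1], box[2], box[3]), con)
    body <- sprintf(fmt, fr$element, fr$x, fr$y, fr$z, fr$label)
    if (!is.null(fr$charge)) body <- paste(body, sprintf("%.6f", fr$charge))
    if (!is.null(fr$radius)) body <- paste(body, sprintf("%.6f", fr$radius))
    writeLines(body, con)
  }
  invisible(path)
}
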