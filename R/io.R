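#' Species naming convention for structure files
#'
#' Mapping between the internal species tags and the residue/atom names used
#' when writing or reading GRO/PDB files. For each residue name, atom names
#' are matched by prefix (longest prefix wins). The same table ships as an
#' editable YAML file in `inst/extdata/species_map.yaml`; pass a custom map
#' (or a YAML path) to the readers to override it.
#'
#' @return Nested list: `map[[resname]][[atom_prefix]] = species`.
#' @export
default_species_map <- function() {
  list(
    LIP = list(HD = "LIPID_HEAD", TL = "LIPID_TAIL"),
    DDA = list(C = "DDA_C", O = "DDA_O", H = "DDA_H"),
    SOL = list(OW = "WATER_O", HW = "WATER_H"),
    FLV = list(FL = "FLAV")
  )
}

.load_species_map <- function(species_map) {
  if (is.null(species_map)) return(default_species_map())
  if (is.character(species_map)) return(yaml::read_yaml(species_map))
  species_map
}

# residue + atom names for writing, one row per particle
.names_for_species <- function(frame) {
  sp <- frame$species
  res <- c(LIPID_HEAD = "LIP", LIPID_TAIL = "LIP", DDA_C = "DDA",
           DDA_O = "DDA", DDA_H = "DDA", WATER_O = "SOL", WATER_H = "SOL",
           FLAV = "FLV")[sp]
  atom <- character(length(sp))
  # per-molecule counters give unique-ish atom names (GRO needs none strictly)
  for (m in unique(frame$molecule_id)) {
    i <- which(frame$molecule_id == m)
    s <- sp[i]
    a <- character(length(i))
    a[s == "LIPID_HEAD"] <- "HD1"
    a[s == "LIPID_TAIL"] <- paste0("TL", seq_len(sum(s == "LIPID_TAIL")))
    a[s == "DDA_C"] <- paste0("C", seq_len(sum(s == "DDA_C")))
    a[s == "DDA_O"] <- paste0("O", seq_len(sum(s == "DDA_O")))
    a[s == "DDA_H"] <- paste0("H", seq_len(sum(s == "DDA_H")))
    a[s == "WATER_O"] <- "OW"
    a[s == "WATER_H"] <- paste0("HW", seq_len(sum(s == "WATER_H")))
    a[s == "FLAV"] <- "FL1"
    atom[i] <- a
  }
  list(res = res, atom = atom)
}

.species_from_names <- function(res, atom, map) {
  out <- rep(NA_character_, length(res))
  for (i in seq_along(res)) {
    rmap <- map[[res[i]]]
    if (is.null(rmap)) next
    pref <- names(rmap)
    hit <- pref[startsWith(atom[i], pref)]
    if (length(hit)) out[i] <- rmap[[hit[which.max(nchar(hit))]]]
  }
  if (anyNA(out)) {
    bad <- unique(paste(res[is.na(out)], atom[is.na(out)]))
    stop("unknown residue/atom name(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Write a trajectory to a structure file
#'
#' Supported dialects: multi-frame GRO (box line in nm), PDB with a CRYST1
#' record (coordinates in Angstrom, frames as MODEL blocks), and extended XYZ
#' with a `box="Lx Ly Lz"` comment (nm, internal species tags as atom labels).
#' On write, z is shifted by +Lz/2 so file coordinates lie inside the box;
#' the readers undo the shift, so in-memory frames keep the midplane near
#' z = 0.
#'
#' @param traj an [mp_trajectory] or single [mp_frame].
#' @param path output path.
#' @param format one of `"gro"`, `"pdb"`, `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("gro", "pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(traj, "mp_frame")) traj <- mp_trajectory(list(traj))
  lines <- switch(format,
    gro = unlist(lapply(traj$frames, .frame_to_gro)),
    pdb = c(unlist(lapply(seq_along(traj$frames), function(i)
              .frame_to_pdb(traj$frames[[i]], i))), "END"),
    xyz = unlist(lapply(traj$frames, .frame_to_xyz)))
  writeLines(lines, path)
  invisible(path)
}

.frame_to_gro <- function(fr) {
  nm <- .names_for_species(fr)
  Lz <- fr$box[3]
  n <- nrow(fr$positions)
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  fr$molecule_id %% 100000L, nm$res, nm$atom,
                  seq_len(n) %% 100000L,
                  fr$positions[, 1], fr$positions[, 2],
                  fr$positions[, 3] + Lz / 2)
  c("synthetic bilayer frame", sprintf("%5d", n), body,
    sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
}

.frame_to_pdb <- function(fr, model) {
  nm <- .names_for_species(fr)
  Lz <- fr$box[3]
  n <- nrow(fr$positions)
  c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            fr$box[1] * 10, fr$box[2] * 10, fr$box[3] * 10, 90, 90, 90),
    sprintf("MODEL     %4d", model),
    sprintf("ATOM  %5d %-4s%-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(n) %% 100000L, substr(nm$atom, 1, 4), substr(nm$res, 1, 4),
            fr$molecule_id %% 10000L,
            fr$positions[, 1] * 10, fr$positions[, 2] * 10,
            (fr$positions[, 3] + Lz / 2) * 10),
    "ENDMDL")
}

.frame_to_xyz <- function(fr) {
  n <- nrow(fr$positions)
  c(sprintf("%d", n),
    sprintf("box=\"%.6f %.6f %.6f\" mol=\"%s\"",
            fr$box[1], fr$box[2], fr$box[3],
            paste(fr$molecule_id, collapse = " ")),
    sprintf("%-10s %12.6f %12.6f %12.6f", fr$species,
            fr$positions[, 1], fr$positions[, 2], fr$positions[, 3]))
}

#' Read a trajectory from a structure file
#'
#' Counterpart of [write_trajectory()]. Species are inferred from the
#' residue/atom naming convention (see [default_species_map()]); a missing
#' box record is an error, as is any residue/atom name not covered by the
#' map. Coordinates are returned in nm with the box midplane at z = 0.
#'
#' @param path input file.
#' @param format `"gro"`, `"pdb"` or `"xyz"`; default guesses from the
#'   file extension.
#' @param species_map optional species map (list, or path to a YAML file).
#' @param frame_interval ns between frames (metadata).
#' @return An [mp_trajectory].
#' @export
read_trajectory <- function(path, format = NULL, species_map = NULL,
                            frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "pdb", "xyz"))
  map <- .load_species_map(species_map)
  lines <- readLines(path)
  frames <- switch(format,
                   gro = .gro_frames(lines, map),
                   pdb = .pdb_frames(lines, map),
                   xyz = .xyz_frames(lines))
  mp_trajectory(frames, frame_interval = frame_interval)
}

.gro_frames <- function(lines, map) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO: bad atom count at line ", i + 1L)
    body <- lines[i + 1L + seq_len(n)]
    boxline <- lines[i + 2L + n]
    if (is.na(boxline) || !nzchar(trimws(boxline)))
      stop("GRO frame without box line (box is mandatory)")
    box <- as.numeric(strsplit(trimws(boxline), "\\s+")[[1]])[1:3]
    if (anyNA(box)) stop("GRO frame without box line (box is mandatory)")
    resid <- as.integer(substr(body, 1, 5))
    res <- trimws(substr(body, 6, 10))
    atom <- trimws(substr(body, 11, 15))
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44)) - box[3] / 2
    sp <- .species_from_names(res, atom, map)
    frames[[length(frames) + 1L]] <- mp_frame(cbind(x, y, z), sp, resid, box)
    i <- i + 3L + n
  }
  if (!length(frames)) stop("no frames found in GRO file")
  frames
}

.pdb_frames <- function(lines, map) {
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cry)) stop("PDB file without CRYST1 record (box is mandatory)")
  box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                      substr(cry[1], 25, 33))) / 10
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts)) {
    ends <- grep("^ENDMDL", lines)
    Map(function(s, e) lines[(s + 1):(e - 1)], starts, ends)
  } else list(grep("^ATOM", lines, value = TRUE))
  lapply(blocks, function(b) {
    b <- grep("^ATOM", b, value = TRUE)
    atom <- trimws(substr(b, 13, 16))
    res <- trimws(substr(b, 17, 20))
    resid <- as.integer(substr(b, 21, 26))
    x <- as.numeric(substr(b, 31, 38)) / 10
    y <- as.numeric(substr(b, 39, 46)) / 10
    z <- as.numeric(substr(b, 47, 54)) / 10 - box[3] / 2
    sp <- .species_from_names(res, atom, map)
    mp_frame(cbind(x, y, z), sp, resid, box)
  })
}

.xyz_frames <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    bm <- regmatches(comment, regexec("box=\"([^\"]+)\"", comment))[[1]]
    if (length(bm) < 2) stop("XYZ frame without box=\"...\" comment (box is mandatory)")
    box <- as.numeric(strsplit(trimws(bm[2]), "\\s+")[[1]])
    mm <- regmatches(comment, regexec("mol=\"([^\"]+)\"", comment))[[1]]
    body <- lines[i + 1L + seq_len(n)]
    tok <- strsplit(trimws(body), "\\s+")
    sp <- vapply(tok, `[`, character(1), 1)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    mol <- if (length(mm) >= 2) as.integer(strsplit(trimws(mm[2]), "\\s+")[[1]])
           else cumsum(!duplicated(seq_len(n)))  # fallback: one molecule per atom
    frames[[length(frames) + 1L]] <- mp_frame(xyz, sp, mol, box)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in XYZ file")
  frames
}
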