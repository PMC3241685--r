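# Text file formats.  The frame format is a lossless dialect for full
# simulation state (positions, velocities, dipole orientations and
# angular velocities, box, time), written at full double precision so
# write -> read round trips are bit identical.  PDB/XYZ exports are lossy
# visualisation aids.

.frame_magic <- "#elbamd-frames-v1"

.pkg_version <- function() {
  as.character(utils::packageVersion("elbamd"))
}

#' Write simulation frames to a text file
#'
#' Writes an `elba_system` (one frame, full state) or an
#' `elba_trajectory` (stored frames; velocities/angular velocities are
#' not recorded in trajectories and are written as zero).  Dipole fields
#' are present exactly for the site types carrying a dipole.  The header
#' embeds the package version, the force-field checksum and the seed for
#' provenance.
#'
#' @param x An `elba_system` or `elba_trajectory`.
#' @param path Output file.
#' @param ff The force field (identifies dipole-carrying types).
#' @param seed Seed to record in the header (provenance only).
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, ff = elba_forcefield(), seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s version=%s ff_checksum=%s seed=%s",
                     .frame_magic, .pkg_version(),
                     x$ff_checksum, as.character(seed)), con)
  has_dip <- ff$sites$dipole > 0

  write_one <- function(pos, vel, u, om, box, time, meta) {
    writeLines(sprintf("FRAME time=%.17g box=%.17g,%.17g,%.17g n=%d",
                       time, box[1], box[2], box[3], nrow(pos)), con)
    for (i in seq_len(nrow(pos))) {
      base <- sprintf("%d %s %s %d %d %.17g %.17g %.17g %.17g %.17g %.17g",
                      meta$mol[i], meta$species[i], meta$site_name[i],
                      meta$type[i],
                      ifelse(is.na(meta$leaflet[i]), -1L, meta$leaflet[i]),
                      pos[i, 1], pos[i, 2], pos[i, 3],
                      vel[i, 1], vel[i, 2], vel[i, 3])
      if (has_dip[meta$type[i]])
        base <- paste(base, sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                                    u[i, 1], u[i, 2], u[i, 3],
                                    om[i, 1], om[i, 2], om[i, 3]))
      writeLines(base, con)
    }
  }

  if (inherits(x, "elba_system")) {
    write_one(x$pos, x$vel, x$u, x$omega, x$box, x$time, x)
  } else if (inherits(x, "elba_trajectory")) {
    n <- dim(x$pos)[2]
    zero <- matrix(0, n, 3)
    for (f in seq_len(dim(x$pos)[3]))
      write_one(t(x$pos[, , f]), zero, t(x$u[, , f]), zero,
                x$box[f, ], x$time[f], x)
  } else stop("x must be an elba_system or elba_trajectory")
  invisible(path)
}

#' Read simulation frames
#'
#' Reads a file written by [write_frames()] and reconstructs one
#' `elba_system` per frame, including the bonded topology (rebuilt from
#' the per-molecule species via [make_template()]).  Malformed lines
#' raise an error naming the line number; a truncated frame raises an
#' error naming the expected and found site counts, and no partial frame
#' is returned.
#'
#' @param path Input file.
#' @param ff The force field used when the frames were written.
#' @return List of `elba_system` objects.
#' @export
read_frames <- function(path, ff = elba_forcefield()) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], .frame_magic))
    stop("not an elbamd frame file: ", path)
  has_dip <- ff$sites$dipole > 0
  frames <- list()
  ln <- 2L
  while (ln <= length(lines)) {
    hdr <- lines[ln]
    if (!startsWith(hdr, "FRAME "))
      stop("line ", ln, ": expected FRAME header, got: ", hdr)
    time <- as.numeric(sub(".*time=([^ ]+).*", "\\1", hdr))
    box <- as.numeric(strsplit(sub(".*box=([^ ]+).*", "\\1", hdr), ",")[[1]])
    n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
    if (is.na(time) || length(box) != 3 || is.na(n))
      stop("line ", ln, ": malformed FRAME header")
    avail <- length(lines) - ln
    if (avail < n)
      stop("truncated frame at line ", ln, ": expected ", n,
           " site lines, found ", avail)
    body <- lines[(ln + 1):(ln + n)]
    pos <- vel <- u <- om <- matrix(0, n, 3)
    mol <- type <- leaflet <- integer(n)
    species <- site_name <- character(n)
    for (i in seq_len(n)) {
      tok <- strsplit(body[i], " ", fixed = TRUE)[[1]]
      if (length(tok) < 11)
        stop("line ", ln + i, ": malformed site line (", length(tok),
             " fields)")
      mol[i] <- as.integer(tok[1])
      species[i] <- tok[2]; site_name[i] <- tok[3]
      type[i] <- as.integer(tok[4])
      lf <- as.integer(tok[5]); leaflet[i] <- if (lf < 0) NA_integer_ else lf
      nums <- as.numeric(tok[6:length(tok)])
      if (anyNA(nums)) stop("line ", ln + i, ": non-numeric field")
      pos[i, ] <- nums[1:3]; vel[i, ] <- nums[4:6]
      if (has_dip[type[i]]) {
        if (length(nums) < 12)
          stop("line ", ln + i, ": dipole fields missing for type ",
               ff$sites$name[type[i]])
        u[i, ] <- nums[7:9]; om[i, ] <- nums[10:12]
      }
    }
    sys <- .new_system(ff, box)
    sys$pos <- pos; sys$vel <- vel; sys$u <- u; sys$omega <- om
    sys$type <- type; sys$mol <- mol; sys$leaflet <- leaflet
    sys$group <- ifelse(species == "water", 0L, 1L)
    sys$species <- species; sys$site_name <- site_name
    sys$time <- time
    # rebuild per-molecule topology and electron bookkeeping
    sys$electrons <- numeric(n)
    for (m in unique(mol)) {
      idx <- which(mol == m)
      tpl <- make_template(species[idx[1]], ff)
      if (length(idx) != nrow(tpl$sites))
        stop("molecule ", m, ": ", length(idx), " sites, template has ",
             nrow(tpl$sites))
      sys$electrons[idx] <- tpl$sites$electrons
      o <- idx[1] - 1L
      if (nrow(tpl$bonds)) {
        sys$bonds <- rbind(sys$bonds,
                           cbind(tpl$bonds$i + o, tpl$bonds$j + o,
                                 tpl$bonds$kb, tpl$bonds$r0))
        sys$angles <- rbind(sys$angles,
                            cbind(tpl$angles$i + o, tpl$angles$j + o,
                                  tpl$angles$k + o, tpl$angles$ka,
                                  tpl$angles$theta0))
        sys$restraints <- rbind(sys$restraints,
                                cbind(tpl$restraints$site + o,
                                      tpl$restraints$ref_from + o,
                                      tpl$restraints$ref_to + o,
                                      tpl$restraints$kd))
      }
    }
    class(sys) <- "elba_system"
    frames[[length(frames) + 1]] <- sys
    ln <- ln + n + 1L
  }
  frames
}

#' Export a configuration to PDB
#'
#' Lossy visualisation export: CG sites become HETATM records with
#' species-specific residue names (`W`, `DPC`, `DSC`, `DPE`); dipole
#' orientations cannot be represented in PDB and are dropped with a
#' warning.  Coordinates are converted from nm to Angstrom.
#'
#' @param sys An `elba_system`.
#' @param path Output file.
#' @param ff The force field.
#' @return `path`, invisibly.
#' @export
export_pdb <- function(sys, path, ff = elba_forcefield()) {
  if (any(ff$sites$dipole[sys$type] > 0))
    warning("dipole orientations are not representable in PDB and were dropped")
  res <- c(water = "W", DOPC = "DPC", DSPC = "DSC", DOPE = "DPE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                     sys$box[1] * 10, sys$box[2] * 10, sys$box[3] * 10), con)
  el <- c(choline = "N", amine = "N", phosphate = "P", glycerol = "C",
          ester = "O", tail = "C", water = "O")
  tn <- ff$sites$name[sys$type]
  for (i in seq_len(nrow(sys$pos))) {
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i %% 100000, substr(toupper(tn[i]), 1, 4),
      res[[sys$species[i]]], sys$mol[i] %% 10000,
      sys$pos[i, 1] * 10, sys$pos[i, 2] * 10, sys$pos[i, 3] * 10,
      el[[tn[i]]]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Export a configuration to XYZ
#'
#' @inheritParams export_pdb
#' @return `path`, invisibly.
#' @export
export_xyz <- function(sys, path, ff = elba_forcefield()) {
  con <- file(path, "w")
  on.exit(close(con))
  tn <- ff$sites$name[sys$type]
  writeLines(as.character(nrow(sys$pos)), con)
  writeLines(sprintf("elbamd t=%g box=%g,%g,%g", sys$time,
                     sys$box[1], sys$box[2], sys$box[3]), con)
  for (i in seq_len(nrow(sys$pos)))
    writeLines(sprintf("%s %.6f %.6f %.6f", tn[i],
                       sys$pos[i, 1] * 10, sys$pos[i, 2] * 10,
                       sys$pos[i, 3] * 10), con)
  invisible(path)
}

#' Write an energy log as a tab-separated table
#'
#' Columns carry their units in the header comment; the run provenance
#' (package version, force-field checksum) is embedded.
#'
#' @param run An `elba_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_energy_log <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# elbamd %s energy log; ff_checksum=%s",
                     .pkg_version(), run$system$ff_checksum), con)
  writeLines("# units: time ps, energies kJ/mol, T K, P atm, box nm", con)
  utils::write.table(run$elog, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
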