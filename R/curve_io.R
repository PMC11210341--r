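#' Force-distance curve container
#'
#' One AFM approach/(dwell)/retract cycle: piezo position `z` (nm, increasing
#' away from the cell surface) versus force (pN, positive = tensile), with a
#' per-sample segment label and acquisition metadata. The convention follows
#' force-spectroscopy practice: compressive contact forces are negative,
#' pulling (bond-loading) forces positive.
#'
#' @param z piezo position, nm.
#' @param force force, pN; same length as `z`.
#' @param segment character vector of per-sample labels, each one of
#'   `"approach"`, `"dwell"`, `"retract"`, contiguous in that order.
#' @param kc cantilever spring constant, pN/nm.
#' @param velocity retraction (and approach) velocity, nm/s.
#' @param sampling_rate acquisition rate, Hz.
#' @param curve_id identifier string.
#' @param truth optional ground-truth sidecar list (set by the simulator;
#'   never written to the curve file, so analysis code cannot read it by
#'   accident).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, force, segment, kc, velocity, sampling_rate,
                        curve_id = "curve", truth = NULL) {
  fs_check(length(z) == length(force) && length(z) >= 2,
           "`z` and `force` must have equal length >= 2")
  fs_check(length(segment) == length(z), "`segment` must match `z` in length")
  check_pos(kc, "kc")
  check_pos(velocity, "velocity")
  check_pos(sampling_rate, "sampling_rate")
  bad <- setdiff(unique(segment), c("approach", "dwell", "retract"))
  fs_check(length(bad) == 0,
           sprintf("unknown segment label(s): %s", paste(bad, collapse = ", ")))
  r <- rle(segment)$values
  fs_check(identical(r, intersect(c("approach", "dwell", "retract"), r)),
           "segments must be contiguous in the order approach -> dwell -> retract")
  structure(
    list(z = as.numeric(z), force = as.numeric(force),
         segment = as.character(segment), kc = kc, velocity = velocity,
         sampling_rate = sampling_rate, curve_id = as.character(curve_id),
         truth = truth),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve %s> %d samples (%s), kc = %.4g pN/nm, v = %.4g nm/s\n",
              x$curve_id, length(x$z),
              paste(sprintf("%s: %d", names(table(x$segment)), table(x$segment)),
                    collapse = ", "),
              x$kc, x$velocity))
  invisible(x)
}

#' Curve set: curves measured under one condition
#'
#' @param curves list of [force_curve()] objects.
#' @param condition label, e.g. an antibody/cell pairing.
#' @param dwell_time_s nominal tip-surface dwell time per curve, s.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(curves, condition = "condition", dwell_time_s = NA_real_) {
  fs_check(is.list(curves) && length(curves) >= 1, "`curves` must be non-empty")
  fs_check(all(vapply(curves, inherits, logical(1), "force_curve")),
           "all elements of `curves` must be force_curve objects")
  kcs <- vapply(curves, `[[`, numeric(1), "kc")
  fs_check(all(is.finite(kcs)), "curves must carry finite spring constants")
  structure(list(curves = curves, condition = condition,
                 dwell_time_s = dwell_time_s),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set '%s'> %d curves, nominal dwell %.4g s\n",
              x$condition, length(x$curves), x$dwell_time_s))
  invisible(x)
}

#' @export
length.curve_set <- function(x) length(x$curves)

MANDATORY_KEYS <- c("curve_id", "spring_constant_pN_per_nm",
                    "velocity_nm_per_s", "sampling_hz")

#' Read and write force curves in the plain-text dialect
#'
#' Curves are stored as UTF-8 TSV: header lines `# key<TAB>value` carrying the
#' mandatory keys `curve_id`, `spring_constant_pN_per_nm`, `velocity_nm_per_s`
#' and `sampling_hz`, then a column header `z_nm<TAB>force_pN<TAB>segment`,
#' then one row per sample. `z` increases away from the surface; positive
#' force is tensile. The round trip write -> read is lossless to the printed
#' precision (17 significant digits, i.e. exact for doubles).
#'
#' @param path file path.
#' @param curve a [force_curve()].
#' @return `read_curve()` returns a [force_curve()]; `write_curve()` returns
#'   `path` invisibly. Ground-truth sidecar data are never written.
#' @export
read_curve <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- startsWith(lines, "# ")
  meta <- list()
  for (i in which(is_header)) {
    kv <- strsplit(sub("^# ", "", lines[i]), "\t", fixed = TRUE)[[1]]
    fs_check(length(kv) == 2,
             sprintf("line %d: malformed header line", i),
             class = "forcespec_format_error")
    meta[[kv[1]]] <- kv[2]
  }
  missing <- setdiff(MANDATORY_KEYS, names(meta))
  if (length(missing) > 0)
    fs_abort(sprintf("missing mandatory header key(s): %s",
                     paste(missing, collapse = ", ")),
             class = "forcespec_format_error")
  body <- lines[!is_header]
  fs_check(length(body) >= 2 && identical(body[1], "z_nm\tforce_pN\tsegment"),
           "expected column header 'z_nm\tforce_pN\tsegment'",
           class = "forcespec_format_error")
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nline <- which(!is_header)[-1]  # file line numbers of data rows
  nf <- lengths(rows)
  if (any(nf != 3))
    fs_abort(sprintf("line %d: expected 3 tab-separated fields",
                     nline[which(nf != 3)[1]]),
             class = "forcespec_format_error")
  m <- matrix(unlist(rows, use.names = FALSE), ncol = 3, byrow = TRUE)
  z <- suppressWarnings(as.numeric(m[, 1]))
  force <- suppressWarnings(as.numeric(m[, 2]))
  segment <- m[, 3]
  if (anyNA(z) || anyNA(force))
    fs_abort(sprintf("line %d: non-numeric z or force",
                     nline[which(is.na(z) | is.na(force))[1]]),
             class = "forcespec_format_error")
  bad_seg <- !segment %in% c("approach", "dwell", "retract")
  if (any(bad_seg))
    fs_abort(sprintf("line %d: unknown segment label '%s'",
                     nline[which(bad_seg)[1]], segment[which(bad_seg)[1]]),
             class = "forcespec_format_error")
  force_curve(z, force, segment,
              kc = as.numeric(meta$spring_constant_pN_per_nm),
              velocity = as.numeric(meta$velocity_nm_per_s),
              sampling_rate = as.numeric(meta$sampling_hz),
              curve_id = meta$curve_id)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  fs_check(inherits(curve, "force_curve"), "`curve` must be a force_curve")
  num <- function(x) formatC(x, digits = 17, format = "g")
  hdr <- c(
    sprintf("# curve_id\t%s", curve$curve_id),
    sprintf("# spring_constant_pN_per_nm\t%s", num(curve$kc)),
    sprintf("# velocity_nm_per_s\t%s", num(curve$velocity)),
    sprintf("# sampling_hz\t%s", num(curve$sampling_rate))
  )
  body <- paste(num(curve$z), num(curve$force), curve$segment, sep = "\t")
  writeLines(c(hdr, "z_nm\tforce_pN\tsegment", body), path, useBytes = TRUE)
  invisible(path)
}

#' Read/write a curve set via a JSON manifest
#'
#' The manifest lists per-curve file paths (relative to the manifest) plus the
#' condition label and nominal dwell time; ground-truth labels, when present,
#' go to a separate `<stem>_truth.json` sidecar.
#'
#' @param cs a [curve_set()].
#' @param dir directory to write into (created if needed).
#' @param stem file-name stem for the manifest and curve files.
#' @param path manifest path for reading.
#' @return `write_curve_set()`: the manifest path, invisibly.
#'   `read_curve_set()`: a [curve_set()] (without truth sidecars).
#' @export
write_curve_set <- function(cs, dir, stem = "curves") {
  fs_check(inherits(cs, "curve_set"), "`cs` must be a curve_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%04d.tsv", stem, seq_along(cs$curves))
  for (i in seq_along(cs$curves)) {
    write_curve(cs$curves[[i]], file.path(dir, files[i]))
  }
  truths <- lapply(cs$curves, `[[`, "truth")
  if (any(!vapply(truths, is.null, logical(1)))) {
    names(truths) <- vapply(cs$curves, `[[`, character(1), "curve_id")
    jsonlite::write_json(truths, file.path(dir, paste0(stem, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- list(condition = cs$condition, dwell_time_s = cs$dwell_time_s,
                   curves = files)
  mpath <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname write_curve_set
#' @export
read_curve_set <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  curves <- lapply(file.path(dir, m$curves), read_curve)
  curve_set(curves, condition = m$condition, dwell_time_s = m$dwell_time_s)
}

#' Tip-surface dwell time of a force curve
#'
#' The dwell time is the duration the tip (and hence the tethered ligand) can
#' reach receptors during one cycle: the contact extent travelled on the
#' approach plus that on the retract, divided by the vertical scanning speed,
#' plus the duration of any explicit constant-contact dwell segment.
#'
#' The contact extent is either supplied (`contact_extent_nm`, one-sided, used
#' for both approach and retract) or auto-detected as the region where the
#' force magnitude exceeds `threshold_factor` times the baseline noise sd
#' (robust MAD estimate over the non-contact part of the approach).
#'
#' @param curve a [force_curve()].
#' @param contact_extent_nm optional one-sided contact extent, nm.
#' @param threshold_factor contact-detection threshold in baseline sd units.
#' @return Dwell time in seconds.
#' @examples
#' # 150 nm contact on each of approach and retract at 3000 nm/s -> 0.1 s
#' @export
compute_dwell_time <- function(curve, contact_extent_nm = NULL,
                               threshold_factor = 2) {
  fs_check(inherits(curve, "force_curve"), "`curve` must be a force_curve")
  check_pos(curve$velocity, "velocity")
  seg <- curve$segment
  dwell_extra <- sum(seg == "dwell") / curve$sampling_rate
  if (!is.null(contact_extent_nm)) {
    fs_check(is.numeric(contact_extent_nm) && contact_extent_nm >= 0,
             "`contact_extent_nm` must be >= 0")
    return(2 * contact_extent_nm / curve$velocity + dwell_extra)
  }
  extent_of <- function(idx) {
    if (length(idx) < 2) return(0)
    f <- curve$force[idx]; z <- curve$z[idx]
    # baseline from the half of the segment farthest from the surface
    far <- z > stats::median(z)
    sd0 <- stats::mad(f[far])
    if (!is.finite(sd0) || sd0 == 0) sd0 <- stats::sd(f[far])
    if (!is.finite(sd0) || sd0 == 0) sd0 <- .Machine$double.eps
    # contact = repulsive (compressive, negative) force; tensile tether
    # stretch on the retract is not tip-surface contact
    contact <- f < -threshold_factor * sd0
    if (!any(contact)) return(0)
    # keep only the contact cluster adjacent to the surface: walk up from the
    # lowest z and stop at the first large gap, so isolated noise crossings
    # far from the surface do not inflate the extent
    zc <- sort(z[contact])
    gap <- 10 * stats::median(diff(sort(z)))
    dzc <- diff(zc)
    brk <- which(dzc > gap)
    top <- if (length(brk) > 0) zc[min(brk)] else max(zc)
    keep <- z[contact] >= min(zc) & z[contact] <= top
    zcl <- z[contact][keep]; fcl <- f[contact][keep]
    # the threshold crossing clips ~sd0/slope of true extent; extrapolate the
    # contact ramp to its zero-force crossing instead
    if (length(zcl) >= 5 && stats::sd(zcl) > 0) {
      co <- stats::coef(stats::lm(fcl ~ zcl))
      if (is.finite(co[2]) && co[2] > 0) {
        z0 <- unname(-co[1] / co[2])
        if (z0 > top && z0 < top + 5 * gap) top <- z0
      }
    }
    top - min(zcl)
  }
  ext_app <- extent_of(which(seg == "approach"))
  ext_ret <- extent_of(which(seg == "retract"))
  (ext_app + ext_ret) / curve$velocity + dwell_extra
}
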