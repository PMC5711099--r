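## Minimal DICOM RT Structure Set I/O, explicit VR little endian.
## Only the mandatory modules needed to carry closed planar contours are
## written; the reader handles defined- and undefined-length sequences.

UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPL <- "2.25.437601"

u16raw <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
u32raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
r_u16 <- function(b, p) as.integer(b[p]) + 256L * as.integer(b[p + 1L])
r_u32 <- function(b, p) as.integer(b[p]) + 256 * as.integer(b[p + 1L]) +
  65536 * as.integer(b[p + 2L]) + 16777216 * as.integer(b[p + 3L])

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

enc_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
  }
  if (length(value) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value <- c(value, pad)
  }
  hdr <- c(u16raw(group), u16raw(element), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(hdr, as.raw(c(0, 0)), u32raw(length(value)), value)
  } else {
    stopifnot(length(value) < 65536)
    c(hdr, u16raw(length(value)), value)
  }
}

enc_item <- function(content) c(u16raw(0xFFFE), u16raw(0xE000), u32raw(length(content)), content)

enc_sq <- function(group, element, items) {
  body <- do.call(c, c(list(raw(0)), items))
  enc_element(group, element, "SQ", body)
}

fmt_ds <- function(x) {
  s <- sprintf("%.6f", x)
  # DS values are limited to 16 bytes
  ifelse(nchar(s) > 16L, substr(s, 1L, 16L), s)
}

new_uid <- function(salt) {
  sprintf("2.25.%d%d", abs(salt) %% 1000000L, 100000L + (abs(salt * 7919L) %% 900000L))
}

#' Write a contour set as a DICOM RT Structure Set
#'
#' Serializes the contours as a standard RT Structure Set (explicit VR
#' little endian, minimal mandatory modules, no vendor private tags).
#' Contour points are written as x,y,z decimal strings with 6 decimals, so
#' the per-coordinate quantization error is at most 5e-7 mm. The boundary
#' dialect is carried in the structure-set description so a round trip
#' restores it.
#'
#' @param cs a \code{\link{contour_set}}.
#' @param path output file path.
#' @param image_meta optional list with \code{patient_name},
#'   \code{patient_id}, \code{study_uid}, \code{series_uid}.
#' @return \code{path}, invisibly.
#' @export
write_rtstruct <- function(cs, path, image_meta = list()) {
  stopifnot(inherits(cs, "contour_set"))
  meta <- utils::modifyList(list(patient_name = "PHANTOM^CASE",
                                 patient_id = "PHANTOM",
                                 study_uid = new_uid(1L),
                                 series_uid = new_uid(2L)), image_meta)
  sop_uid <- new_uid(3L + length(cs$contours))

  ssroi <- enc_item(c(
    enc_element(0x3006, 0x0022, "IS", "1"),
    enc_element(0x3006, 0x0024, "UI", cs$frame_uid),
    enc_element(0x3006, 0x0026, "LO", cs$name),
    enc_element(0x3006, 0x0036, "CS", "AUTOMATIC")))

  contour_items <- lapply(cs$contours, function(ct) {
    xyz <- cbind(ct$points, ct$z)
    ds <- paste(fmt_ds(t(xyz)), collapse = "\\")
    enc_item(c(
      enc_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
      enc_element(0x3006, 0x0046, "IS", as.character(nrow(ct$points))),
      enc_element(0x3006, 0x0050, "DS", ds)))
  })
  roi_contour <- enc_item(c(
    enc_sq(0x3006, 0x0040, contour_items),
    enc_element(0x3006, 0x0084, "IS", "1")))

  frame_item <- enc_item(enc_element(0x0020, 0x0052, "UI", cs$frame_uid))

  dataset <- c(
    enc_element(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    enc_element(0x0008, 0x0018, "UI", sop_uid),
    enc_element(0x0008, 0x0020, "DA", ""),
    enc_element(0x0008, 0x0030, "TM", ""),
    enc_element(0x0008, 0x0050, "SH", ""),
    enc_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    enc_element(0x0008, 0x0090, "PN", ""),
    enc_element(0x0010, 0x0010, "PN", meta$patient_name),
    enc_element(0x0010, 0x0020, "LO", meta$patient_id),
    enc_element(0x0010, 0x0030, "DA", ""),
    enc_element(0x0010, 0x0040, "CS", ""),
    enc_element(0x0020, 0x000D, "UI", meta$study_uid),
    enc_element(0x0020, 0x000E, "UI", meta$series_uid),
    enc_element(0x0020, 0x0010, "SH", "1"),
    enc_element(0x0020, 0x0011, "IS", "1"),
    enc_element(0x3006, 0x0002, "SH", cs$name),
    enc_element(0x3006, 0x0006, "ST", cs$dialect),
    enc_element(0x3006, 0x0008, "DA", ""),
    enc_element(0x3006, 0x0009, "TM", ""),
    enc_sq(0x3006, 0x0010, list(frame_item)),
    enc_sq(0x3006, 0x0020, list(ssroi)),
    enc_sq(0x3006, 0x0039, list(roi_contour)))

  meta_body <- c(
    enc_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    enc_element(0x0002, 0x0002, "UI", UID_RTSTRUCT),
    enc_element(0x0002, 0x0003, "UI", sop_uid),
    enc_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    enc_element(0x0002, 0x0012, "UI", UID_IMPL))
  file_meta <- c(enc_element(0x0002, 0x0000, "UL", u32raw(length(meta_body))), meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), file_meta, dataset), con)
  invisible(path)
}

## --- parser ---------------------------------------------------------------

## parse elements in b[(p)..(end)]; returns list of elements, each
## list(group, element, vr, value(raw), items(list of element lists))
parse_elements <- function(b, p, end, path = "") {
  out <- list()
  while (p <= end) {
    if (p + 7L > length(b) + 1L)
      stop(sprintf("truncated element header at %s offset %d", path, p))
    group <- r_u16(b, p); element <- r_u16(b, p + 2L)
    tagstr <- sprintf("%s/(%04X,%04X)", path, group, element)
    if (group == 0xFFFE) {
      # item delimiters handled by the sequence parser; here means malformed
      stop(sprintf("unexpected item tag at %s", tagstr))
    }
    vr <- rawToChar(b[(p + 4L):(p + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("malformed VR at %s", tagstr))
    if (vr %in% long_vrs) {
      len <- r_u32(b, p + 8L)
      vstart <- p + 12L
    } else {
      len <- r_u16(b, p + 6L)
      vstart <- p + 8L
    }
    el <- list(group = group, element = element, vr = vr, value = raw(0), items = NULL)
    if (vr == "SQ") {
      if (len == 4294967295) {  # undefined length: scan to sequence delimiter
        res <- parse_sq_items(b, vstart, NA, tagstr)
      } else {
        res <- parse_sq_items(b, vstart, vstart + len - 1L, tagstr)
      }
      el$items <- res$items
      p <- res$next_p
    } else {
      if (vstart + len - 1L > length(b))
        stop(sprintf("value overruns file at %s", tagstr))
      el$value <- if (len > 0) b[vstart:(vstart + len - 1L)] else raw(0)
      p <- vstart + len
    }
    out[[length(out) + 1L]] <- el
  }
  out
}

parse_sq_items <- function(b, p, end, path) {
  items <- list()
  repeat {
    if (!is.na(end) && p > end) break
    if (p + 7L > length(b) + 1L) {
      if (is.na(end)) stop(sprintf("unterminated sequence at %s", path))
      break
    }
    group <- r_u16(b, p); element <- r_u16(b, p + 2L)
    len <- r_u32(b, p + 4L)
    if (group == 0xFFFE && element == 0xE0DD) { p <- p + 8L; break }  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop(sprintf("expected item tag inside %s", path))
    if (len == 4294967295) {
      # undefined-length item: parse until item delimiter
      q <- p + 8L
      sub <- list();
      repeat {
        g2 <- r_u16(b, q); e2 <- r_u16(b, q + 2L)
        if (g2 == 0xFFFE && e2 == 0xE00D) { q <- q + 8L; break }
        one <- parse_one(b, q, sprintf("%s/item%d", path, length(items) + 1L))
        sub[[length(sub) + 1L]] <- one$el
        q <- one$next_p
      }
      items[[length(items) + 1L]] <- sub
      p <- q
    } else {
      items[[length(items) + 1L]] <-
        parse_elements(b, p + 8L, p + 7L + len, sprintf("%s/item%d", path, length(items) + 1L))
      p <- p + 8L + len
    }
  }
  list(items = items, next_p = p)
}

parse_one <- function(b, p, path) {
  els <- NULL
  # parse exactly one element by delegating with a trick: parse header length
  group <- r_u16(b, p); element <- r_u16(b, p + 2L)
  vr <- rawToChar(b[(p + 4L):(p + 5L)])
  if (vr %in% long_vrs) {
    len <- r_u32(b, p + 8L); vstart <- p + 12L
  } else {
    len <- r_u16(b, p + 6L); vstart <- p + 8L
  }
  if (vr == "SQ") {
    res <- if (len == 4294967295) parse_sq_items(b, vstart, NA, path)
           else parse_sq_items(b, vstart, vstart + len - 1L, path)
    list(el = list(group = group, element = element, vr = vr, value = raw(0),
                   items = res$items), next_p = res$next_p)
  } else {
    list(el = list(group = group, element = element, vr = vr,
                   value = if (len > 0) b[vstart:(vstart + len - 1L)] else raw(0),
                   items = NULL),
         next_p = vstart + len)
  }
}

find_el <- function(els, group, element) {
  for (el in els) if (el$group == group && el$element == element) return(el)
  NULL
}

el_string <- function(el) {
  if (is.null(el) || length(el$value) == 0L) return("")
  v <- el$value
  while (length(v) > 0L && v[length(v)] == as.raw(0L)) v <- v[-length(v)]
  sub(" +$", "", rawToChar(v))
}

#' Read a DICOM RT Structure Set
#'
#' Parses an explicit-VR little-endian RT Structure Set written by
#' \code{\link{write_rtstruct}} (or any conforming writer using that
#' transfer syntax) and reconstructs the contour set. Malformed files raise
#' an error naming the offending element path.
#'
#' @param path file path.
#' @return A \code{\link{contour_set}}.
#' @export
read_rtstruct <- function(path) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker)")
  # file meta group
  p <- 133L
  glen_el <- parse_one(b, p, "(filemeta)")
  stopifnot(glen_el$el$group == 2L, glen_el$el$element == 0L)
  glen <- r_u32(glen_el$el$value, 1L)
  meta <- parse_elements(b, glen_el$next_p, glen_el$next_p + glen - 1L, "(filemeta)")
  ts <- el_string(find_el(meta, 0x0002, 0x0010))
  if (ts != UID_EXPLICIT_LE)
    stop(sprintf("unsupported transfer syntax '%s'", ts))
  els <- parse_elements(b, glen_el$next_p + glen, length(b), "")

  name <- el_string(find_el(els, 0x3006, 0x0002))
  dialect <- el_string(find_el(els, 0x3006, 0x0006))
  if (!dialect %in% c("voxel_edge", "voxel_center")) dialect <- "voxel_edge"
  frame_uid <- "2.25.0"
  frs <- find_el(els, 0x3006, 0x0010)
  if (!is.null(frs) && length(frs$items) > 0L) {
    fu <- find_el(frs$items[[1L]], 0x0020, 0x0052)
    if (!is.null(fu)) frame_uid <- el_string(fu)
  }
  rcs <- find_el(els, 0x3006, 0x0039)
  if (is.null(rcs)) stop("missing element /(3006,0039) ROIContourSequence")
  contours <- list()
  for (item in rcs$items) {
    cseq <- find_el(item, 0x3006, 0x0040)
    if (is.null(cseq)) next
    for (cit in cseq$items) {
      cd <- find_el(cit, 0x3006, 0x0050)
      if (is.null(cd)) stop("missing element /(3006,0050) ContourData")
      vals <- as.numeric(strsplit(el_string(cd), "\\\\")[[1L]])
      if (length(vals) %% 3L != 0L) stop("ContourData length not a multiple of 3")
      xyz <- matrix(vals, ncol = 3L, byrow = TRUE)
      contours[[length(contours) + 1L]] <- planar_contour(xyz[1L, 3L], xyz[, 1:2])
    }
  }
  contour_set(if (nzchar(name)) name else "ROI", contours, dialect,
              frame_uid = frame_uid)
}
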