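#' Read and write surface structures (XYZ/GRO with a parameter sidecar)
#'
#' XYZ and GRO files carry positions only, so charges and Lennard-Jones
#' parameters travel in a sidecar CSV (columns
#' `index,label,charge_e,epsilon_kJmol,sigma_nm`); the sidecar is part of
#' the round-trip contract. XYZ positions are written in Angstrom (the
#' format's convention) and converted back to nm on read; GRO positions
#' are nm with 3 decimals, so a round trip is exact to 0.0005 nm.
#'
#' @param s a [surface].
#' @param path output structure file.
#' @param format `"xyz"` or `"gro"`; guessed from the file extension when
#'   missing.
#' @param params_path sidecar CSV path; defaults to `path` with a `.csv`
#'   extension appended.
#' @return `write_structure()` returns `path` invisibly; `read_structure()`
#'   returns a [surface].
#' @export
write_structure <- function(s, path, format = c("auto", "xyz", "gro"),
                            params_path = paste0(path, ".csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  a <- s$atoms
  meta <- sprintf("surfriction kind=%s cell=%.6f,%.6f z_plane=%.6f",
                  s$kind, s$cell[1], s$cell[2], s$z_plane)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    writeLines(as.character(nrow(a)), con)
    writeLines(meta, con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                       a$label, a$x * 10, a$y * 10, a$z * 10), con)
  } else if (format == "gro") {
    writeLines(meta, con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1L, "SURF", substr(a$label, 1, 5), seq_len(nrow(a)),
                       a$x, a$y, a$z), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", s$cell[1], s$cell[2],
                       max(3, 2 * max(a$z) + 3)), con)
  } else stop("unknown structure format '", format, "'")
  utils::write.csv(
    data.frame(index = seq_len(nrow(a)), label = a$label,
               charge_e = a$charge, epsilon_kJmol = a$epsilon,
               sigma_nm = a$sigma),
    params_path, row.names = FALSE)
  invisible(path)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "gro")) ext
  else stop("cannot guess structure format from extension '", ext, "'")
}

#' @rdname write_structure
#' @export
read_structure <- function(path, format = c("auto", "xyz", "gro"),
                           params_path = paste0(path, ".csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error at line 1: empty file ", path)
  if (format == "xyz") {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("parse error at line 1: expected atom count")
    if (length(lines) < n + 2)
      stop("parse error at line ", length(lines) + 1,
           ": expected ", n, " atom lines")
    meta <- .parse_meta(lines[2])
    recs <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
    bad <- which(vapply(recs, length, 1L) < 4L)
    if (length(bad))
      stop("parse error at line ", bad[1] + 2, ": need 'element x y z'")
    lab <- vapply(recs, `[[`, "", 1L)
    xyz <- t(vapply(recs, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("parse error: non-numeric coordinate")
    pos <- xyz / 10  # Angstrom -> nm
  } else {
    meta <- .parse_meta(lines[1])
    n <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(n)) stop("parse error at line 2: expected atom count")
    if (length(lines) < n + 3)
      stop("parse error at line ", length(lines) + 1, ": truncated gro file")
    al <- lines[3:(n + 2)]
    lab <- trimws(substr(al, 11, 15))
    pos <- cbind(as.numeric(substr(al, 21, 28)),
                 as.numeric(substr(al, 29, 36)),
                 as.numeric(substr(al, 37, 44)))
    if (anyNA(pos)) stop("parse error: malformed gro coordinate field")
    box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
    if (is.null(meta$cell)) meta$cell <- box[1:2]
  }
  if (!file.exists(params_path))
    stop("sidecar parameter table not found: ", params_path)
  par <- utils::read.csv(params_path)
  if (nrow(par) != nrow(pos))
    stop("sidecar row count (", nrow(par), ") does not match atom count (",
         nrow(pos), ")")
  atoms <- data.frame(label = lab, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      charge = par$charge_e, epsilon = par$epsilon_kJmol,
                      sigma = par$sigma_nm)
  surface(atoms, cell = meta$cell %||% c(max(pos[, 1]), max(pos[, 2])),
          z_plane = meta$z_plane %||% stats::median(pos[, 3]),
          kind = meta$kind %||% "custom",
          metadata = list(source = path))
}

.parse_meta <- function(line) {
  out <- list()
  m <- regmatches(line, regexec("kind=(\\S+)", line))[[1]]
  if (length(m) == 2) out$kind <- m[2]
  m <- regmatches(line, regexec("cell=([0-9.eE+-]+),([0-9.eE+-]+)", line))[[1]]
  if (length(m) == 3) out$cell <- as.numeric(m[2:3])
  m <- regmatches(line, regexec("z_plane=([0-9.eE+-]+)", line))[[1]]
  if (length(m) == 2) out$z_plane <- as.numeric(m[2])
  out
}

#' Read and write multi-frame XYZ trajectories
#'
#' Frames are lists of numeric matrices with columns x, y, z in nm (one
#' row per atom/site); on disk, positions follow the XYZ convention of
#' Angstrom. Water frames with three sites per molecule (O, H, H row
#' order) round-trip through the same functions.
#'
#' @param frames list of n x 3 numeric matrices (nm), or a single matrix.
#' @param path file path.
#' @param labels per-atom element labels recycled across frames.
#' @param comment per-frame comment prefix.
#' @return `read_traj_xyz()` returns a list of matrices (nm).
#' @export
write_traj_xyz <- function(frames, path, labels = "OW", comment = "frame") {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    lab <- rep_len(labels, nrow(f))
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("%s %d", comment, i), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                       lab, f[, 1] * 10, f[, 2] * 10, f[, 3] * 10), con)
  }
  invisible(path)
}

#' @rdname write_traj_xyz
#' @export
read_traj_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error at line 1: empty file ", path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("parse error at line ", i, ": expected atom count")
    if (i + 1 + n > length(lines))
      stop("parse error at line ", length(lines) + 1, ": truncated frame")
    recs <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    xyz <- t(vapply(recs, function(r) as.numeric(r[2:4]), numeric(3))) / 10
    if (anyNA(xyz)) stop("parse error near line ", i + 2,
                         ": non-numeric coordinate")
    rownames(xyz) <- vapply(recs, `[[`, "", 1L)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  frames
}

# extract oxygen (or point-particle) positions from a frame
.o_positions <- function(frame) {
  if (is.list(frame) && !is.data.frame(frame))
    return(t(vapply(frame, function(w) w[1, ], numeric(3))))
  m <- as.matrix(frame)
  labs <- rownames(m)
  if (!is.null(labs) && any(grepl("^H", labs)) && any(!grepl("^H", labs)))
    m <- m[!grepl("^H", labs), , drop = FALSE]
  m
}

# group a site matrix (rows O,H1,H2,O,H1,H2,...) into water_config list
.group_waters <- function(frame) {
  if (is.list(frame) && !is.data.frame(frame)) return(frame)
  m <- as.matrix(frame)
  if (nrow(m) %% 3L != 0L)
    stop("frame has ", nrow(m), " sites, not a multiple of 3")
  lapply(seq_len(nrow(m) / 3L), function(k) {
    w <- m[(3 * k - 2):(3 * k), , drop = FALSE]
    rownames(w) <- c("O", "H1", "H2")
    w
  })
}
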