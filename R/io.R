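BOHR_PER_ANGSTROM <- 1.8897259886

#' Read a cluster geometry from an XYZ-dialect file
#'
#' The comment line (line 2) must declare the length unit through a
#' \code{units=bohr} or \code{units=angstrom} token; there is no silent
#' default.  Angstrom coordinates are converted to bohr (logged).  Two
#' atoms are recognized as a dimer; three equally spaced atoms as a
#' linear or equilateral trimer.
#'
#' @param path file path.
#' @return an \code{\link{hcluster}} when the cluster shape is
#'   recognized, otherwise a list with \code{positions} (bohr) and
#'   \code{tau}.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("read_geometry: truncated XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("read_geometry: first line must be the atom count")
  comment <- lines[2]
  unit <- regmatches(comment, regexpr("units=[A-Za-z]+", comment))
  if (length(unit) == 0) {
    stop("read_geometry: missing units token (units=bohr or units=angstrom)")
  }
  unit <- sub("units=", "", unit)
  if (!unit %in% c("bohr", "angstrom")) {
    stop("read_geometry: unsupported unit '", unit, "'")
  }
  if (length(lines) < 2 + n) stop("read_geometry: fewer atom lines than declared")
  fields <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  tau <- vapply(fields, `[`, character(1), 1)
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(pos)) stop("read_geometry: malformed coordinate line")
  if (unit == "angstrom") {
    message("read_geometry: converting angstrom coordinates to bohr")
    pos <- pos * BOHR_PER_ANGSTROM
  }
  as_hcluster_if_possible(pos, tau)
}

# recognize dimer / linear trimer / equilateral trimer shapes
as_hcluster_if_possible <- function(pos, tau) {
  n <- nrow(pos)
  if (n == 2) {
    g <- hcluster("dimer", sqrt(sum((pos[1, ] - pos[2, ])^2)))
    return(g)
  }
  if (n == 3) {
    D <- as.matrix(stats::dist(pos))
    d <- sort(c(D[1, 2], D[1, 3], D[2, 3]))
    if (abs(d[1] - d[2]) < 1e-8 && abs(d[3] - 2 * d[1]) < 1e-8) {
      return(hcluster("linear_trimer", d[1]))
    }
    if (abs(d[1] - d[3]) < 1e-8) {
      return(hcluster("equilateral_trimer", d[1]))
    }
  }
  list(positions = pos, tau = tau)
}

#' Write a Slater-Koster table to its plain-text format
#'
#' One block per channel: header lines \code{kernel=}, \code{tau_pair=},
#' \code{l_pair=}, \code{m=}, \code{cutoff=}, \code{tail=}, then two
#' columns \code{r value} at full double precision (17 significant
#' digits).  Only grid-backed channels can be serialized.
#'
#' @param table an \code{\link{sk_table}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_sk_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(table$channels)) {
    ch <- table$channels[[key]]
    if (is.null(ch[["grid"]])) {
      stop("write_sk_table: channel ", key, " has no grid representation")
    }
    writeLines(c(
      sprintf("kernel=%s", table$kernel_kind),
      sprintf("tau_pair=%s %s", ch$tau_pair[1], ch$tau_pair[2]),
      sprintf("l_pair=%d %d", ch$l_pair[1], ch$l_pair[2]),
      sprintf("m=%d", ch$m),
      sprintf("cutoff=%.17g", ch$cutoff),
      sprintf("tail=%s", ch$tail)), con)
    writeLines(sprintf("%.17g %.17g", ch[["grid"]]$r, ch[["grid"]]$values),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Slater-Koster table from its plain-text format
#'
#' Inverse of \code{\link{write_sk_table}}; \code{read} after
#' \code{write} reproduces every stored value bit-for-bit.  Malformed
#' headers are reported with their line number.
#'
#' @param path file path.
#' @return an \code{\link{sk_table}}.
#' @export
read_sk_table <- function(path) {
  lines <- readLines(path)
  kernel <- NULL
  channels <- list()
  i <- 1L
  parse_err <- function(i, why) {
    stop(sprintf("read_sk_table: %s at line %d", why, i))
  }
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!startsWith(ln, "kernel=")) parse_err(i, "expected 'kernel=' header")
    kernel <- sub("kernel=", "", ln)
    hdr <- list()
    i <- i + 1L
    while (i <= length(lines) && grepl("=", lines[i], fixed = TRUE)) {
      kv <- strsplit(trimws(lines[i]), "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) parse_err(i, "malformed header")
      hdr[[kv[1]]] <- kv[2]
      i <- i + 1L
    }
    for (need in c("tau_pair", "l_pair", "m", "cutoff", "tail")) {
      if (is.null(hdr[[need]])) parse_err(i, paste0("missing field '", need, "'"))
    }
    if (!hdr$tail %in% c("zero", "monopole")) {
      parse_err(i, "tail must be one of: zero, monopole")
    }
    rr <- c(); vv <- c()
    while (i <= length(lines) && trimws(lines[i]) != "" &&
           !grepl("=", lines[i], fixed = TRUE)) {
      f <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      if (length(f) != 2 || anyNA(f)) parse_err(i, "malformed data line")
      rr <- c(rr, f[1]); vv <- c(vv, f[2])
      i <- i + 1L
    }
    if (length(rr) == 0) parse_err(i, "channel without data")
    tp <- strsplit(hdr$tau_pair, "\\s+")[[1]]
    lp <- as.integer(strsplit(hdr$l_pair, "\\s+")[[1]])
    charges <- if (!is.null(hdr$charges)) {
      as.numeric(strsplit(hdr$charges, "\\s+")[[1]])
    } else c(1, 1)
    channels[[length(channels) + 1L]] <- suppressWarnings(
      radial_channel(tp, lp, as.integer(hdr$m), vv, r = rr,
                     cutoff = as.numeric(hdr$cutoff), tail = hdr$tail,
                     charges = charges))
  }
  if (is.null(kernel)) stop("read_sk_table: empty table file")
  sk_table(kernel, channels)
}

#' Read and validate a run configuration (JSON)
#'
#' Strict schema: unknown keys are rejected; \code{units} must be
#' \code{"atomic"}.
#'
#' @param path JSON file path.
#' @return validated configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("units", "task", "rgrid", "reference_mode", "seed",
               "n_starts", "basis", "trimer_kind", "degeneracy_tol")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("read_run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$units) || cfg$units != "atomic") {
    stop("read_run_config: units must be 'atomic' (hartree, bohr)")
  }
  defaults <- list(task = 1, rgrid = 1.4, reference_mode = "internal_oracle",
                   seed = 12345, n_starts = 20,
                   basis = list(n = 10, alpha0 = 0.02, beta = 2.5),
                   trimer_kind = "linear_trimer", degeneracy_tol = 1e-9)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$task %in% c(1, 2)) stop("read_run_config: task must be 1 or 2")
  if (!cfg$reference_mode %in% c("internal_oracle", "external_adapter")) {
    stop("read_run_config: unsupported reference_mode")
  }
  cfg
}

#' Write a spectrum / reference set as CSV
#'
#' Full-precision, locale-independent serialization of the standard
#' spectrum schema.
#'
#' @param df data frame with columns \code{system, N, Sz, index,
#'   energy_hartree, s2_label}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_spectrum_csv <- function(df, path) {
  df$energy_hartree <- sprintf("%.17g", df$energy_hartree)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum / reference set from CSV
#'
#' @param path CSV path written by \code{\link{write_spectrum_csv}}.
#' @return data frame in the standard spectrum schema.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "N", "Sz", "index", "energy_hartree", "s2_label")
  if (!all(need %in% names(df))) {
    stop("read_spectrum_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
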