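# Built-in scalp electrode table following the international 10-10 layout
# (with 10-5 intermediate rows to reach 128 positions). Positions are placed
# on the unit sphere by the azimuthal-equidistant convention: a cap-plane
# coordinate (u, v) in degrees (u lateral, positive right; v anterior-
# posterior, positive front) maps to inclination sqrt(u^2 + v^2) from the
# vertex and azimuth atan2(v, u), with x = right ear, y = nasion, z = vertex.

cap_direction <- function(u, v) {
  theta <- sqrt(u^2 + v^2) * pi / 180
  phi <- atan2(v, u)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# column index -> lateral angle; odd = left (negative u), even = right
lateral_angle <- function(idx) {
  if (idx == 0L) return(0)
  step <- ceiling(idx / 2) * 18
  if (idx %% 2 == 1L) -step else step
}

cap_row <- function(prefix, v, cols, z_label = paste0(prefix, "z")) {
  labs <- vapply(cols, function(k) {
    if (k == 0L) z_label else paste0(prefix, k)
  }, character(1))
  u <- vapply(cols, lateral_angle, numeric(1))
  data.frame(label = labs, u = u, v = v, stringsAsFactors = FALSE)
}

build_ten_ten_table <- function() {
  full <- c(7L, 5L, 3L, 1L, 0L, 2L, 4L, 6L, 8L)
  # classic 10-20 subset first, so small montages are the familiar cap
  core20 <- data.frame(
    label = c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T7", "C3", "Cz", "C4", "T8",
              "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2"),
    u = c(-18, 0, 18, -72, -36, 0, 36, 72,
          -72, -36, 0, 36, 72,
          -72, -36, 0, 36, 72, -18, 0, 18),
    v = c(72, 72, 72, 36, 36, 36, 36, 36,
          0, 0, 0, 0, 0,
          -36, -36, -36, -36, -36, -72, -72, -72),
    stringsAsFactors = FALSE
  )
  ten10 <- rbind(
    data.frame(label = c("AF7", "AF3", "AFz", "AF4", "AF8"),
               u = c(-54, -18, 0, 18, 54), v = 54, stringsAsFactors = FALSE),
    cap_row("F", 36, c(5L, 1L, 2L, 6L)),
    data.frame(label = c("FT7", "FC5", "FC3", "FC1", "FCz",
                         "FC2", "FC4", "FC6", "FT8"),
               u = vapply(full, lateral_angle, numeric(1)), v = 18,
               stringsAsFactors = FALSE),
    cap_row("C", 0, c(5L, 1L, 2L, 6L)),
    data.frame(label = c("TP7", "CP5", "CP3", "CP1", "CPz",
                         "CP2", "CP4", "CP6", "TP8"),
               u = vapply(full, lateral_angle, numeric(1)), v = -18,
               stringsAsFactors = FALSE),
    cap_row("P", -36, c(5L, 1L, 2L, 6L)),
    data.frame(label = c("PO7", "PO3", "POz", "PO4", "PO8"),
               u = c(-54, -18, 0, 18, 54), v = -54, stringsAsFactors = FALSE)
  )
  # outer 10% ring at 90 degrees inclination
  ring_az <- c(90, -90, 112.5, 67.5, 135, 45, 157.5, 22.5, 180, 0,
               -157.5, -22.5, -135, -45, -112.5, -67.5)
  ring_lab <- c("Nz", "Iz", "AF9", "AF10", "F9", "F10", "FT9", "FT10",
                "T9", "T10", "TP9", "TP10", "P9", "P10", "PO9", "PO10")
  ring <- data.frame(label = ring_lab,
                     u = 90 * cos(ring_az * pi / 180),
                     v = 90 * sin(ring_az * pi / 180),
                     stringsAsFactors = FALSE)
  # 10-5 intermediate rows fill the table out to 128 positions
  inter <- rbind(
    cap_row("AFF", 45, full),
    cap_row("FFC", 27, full),
    cap_row("FCC", 9, full),
    cap_row("CCP", -9, full),
    cap_row("CPP", -27, full),
    cap_row("PPO", -45, full)
  )
  tab <- rbind(core20, ten10, ring, inter)
  tab <- tab[!duplicated(tab$label), ]
  tab <- tab[seq_len(128L), ]
  xyz <- t(vapply(seq_len(nrow(tab)),
                  function(i) cap_direction(tab$u[i], tab$v[i]),
                  numeric(3)))
  tibble::tibble(label = tab$label, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

the_cap <- new.env(parent = emptyenv())

#' Built-in 10-10 scalp electrode table
#'
#' Returns the 128-entry electrode table used by the synthetic head model:
#' labels follow the international 10-10 EEG nomenclature (with 10-5
#' intermediate rows beyond the 81 standard sites), and positions lie on the
#' unit sphere (head radius 1, x toward the right ear, y toward the nasion,
#' z toward the vertex). The first 21 entries are the classic 10-20 montage,
#' so truncating the table to a small `n` still yields a sensible cap.
#'
#' @param n_electrodes Number of leading entries to return (2 to 128).
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @examples
#' ten_ten_cap(4)
#' @export
ten_ten_cap <- function(n_electrodes = 128L) {
  if (is.null(the_cap$table)) the_cap$table <- build_ten_ten_table()
  n <- as.integer(n_electrodes)
  if (is.na(n) || n < 2L) abort("`n_electrodes` must be at least 2.")
  if (n > nrow(the_cap$table)) {
    abort(sprintf("the built-in 10-10 table has %d positions; %d requested.",
                  nrow(the_cap$table), n))
  }
  the_cap$table[seq_len(n), ]
}
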