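# Programmatic molecular fixtures: V2000 molblocks built in code.

make_molblock <- function(title, atoms, bonds, charges = NULL) {
  lines <- c(title, "  ligfish", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(atoms), nrow(bonds)))
  for (i in seq_len(nrow(atoms)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]))
  for (k in seq_len(nrow(bonds)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds$a1[k], bonds$a2[k], bonds$order[k]))
  if (!is.null(charges) && nrow(charges))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", nrow(charges)),
                             paste0(sprintf("%4d%4d", charges$atom, charges$charge),
                                    collapse = "")))
  c(lines, "M  END")
}

write_sdf_records <- function(blocks, path) {
  writeLines(unlist(lapply(blocks, function(b) c(b, "$$$$"))), path)
  path
}

# benzene: regular hexagon, aromatic (order 4) bonds, z = 0
benzene_conformer <- function(id = "benzene", shift = c(0, 0, 0)) {
  ang <- 2 * pi * (0:5) / 6
  conformer(id,
            data.frame(element = rep("C", 6),
                       x = 1.39 * cos(ang) + shift[1],
                       y = 1.39 * sin(ang) + shift[2],
                       z = rep(shift[3], 6)),
            data.frame(a1 = 1:6, a2 = c(2:6, 1), order = rep(4L, 6)))
}

# protonated ethylamine fragment C-C-N(+)
ethylamine_h_conformer <- function(id = "etnh3") {
  conformer(id,
            data.frame(element = c("C", "C", "N"),
                       x = c(0, 1.5, 2.3), y = c(0, 0, 1.2), z = c(0, 0, 0),
                       charge = c(0L, 0L, 1L)),
            data.frame(a1 = c(1, 2), a2 = c(2, 3), order = c(1L, 1L)))
}

# acetamide CH3-C(=O)-NH2: amide N must not be an acceptor
acetamide_conformer <- function(id = "acetamide") {
  conformer(id,
            data.frame(element = c("C", "C", "O", "N"),
                       x = c(0, 1.5, 2.1, 2.2), y = c(0, 0, 1.1, -1.2),
                       z = c(0, 0, 0, 0)),
            data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1L, 2L, 1L)))
}

# acetic acid CH3-C(=O)-OH: ionizable hydroxyl O -> negative PPP
acetic_acid_conformer <- function(id = "acoh") {
  conformer(id,
            data.frame(element = c("C", "C", "O", "O"),
                       x = c(0, 1.5, 2.1, 2.2), y = c(0, 0, 1.1, -1.2),
                       z = c(0, 0, 0, 0)),
            data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1L, 2L, 1L)))
}

# triangle with prescribed side lengths (7.2, 3.4, 5.1)
triangle_ppps <- function(types = c("donor", "acceptor", "lipophilic")) {
  x <- (7.2^2 + 3.4^2 - 5.1^2) / (2 * 7.2)
  y <- sqrt(3.4^2 - x^2)
  data.frame(type = types,
             x = c(0, 7.2, x), y = c(0, 0, y), z = c(0, 0, 0),
             stringsAsFactors = FALSE)
}

# exact rigid motion: 90-degree rotation about z plus integer translation
rigid_motion <- function(xyz) {
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(as.matrix(xyz) %*% t(R), 2, c(3, -2, 5), `+`)
}
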