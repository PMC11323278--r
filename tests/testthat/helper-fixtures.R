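# Toy xyz geometries used throughout (roughly physical bond lengths).
.xyz_texts <- list(
  ch4 = "5\n\nC 0 0 0\nH 0.63 0.63 0.63\nH -0.63 -0.63 0.63\nH -0.63 0.63 -0.63\nH 0.63 -0.63 -0.63",
  ch4_perm = "5\n\nH 0.63 0.63 0.63\nH -0.63 -0.63 0.63\nC 0 0 0\nH -0.63 0.63 -0.63\nH 0.63 -0.63 -0.63",
  h2o = "3\n\nO 0 0 0.1173\nH 0 0.7572 -0.4692\nH 0 -0.7572 -0.4692",
  ethane = paste("8\n\nC 0 0 0\nC 1.54 0 0",
                 "H -0.36 -0.93 -0.4\nH -0.36 0.85 -0.55\nH -0.36 0.08 0.97",
                 "H 1.9 0.93 0.4\nH 1.9 -0.85 0.55\nH 1.9 -0.08 -0.97",
                 sep = "\n"),
  methanol = paste("6\n\nC 0 0 0\nO 1.43 0 0\nH 1.77 0.88 0",
                   "H -0.36 -0.93 -0.4\nH -0.36 0.85 -0.55\nH -0.36 0.08 0.97",
                   sep = "\n")
)

write_toy_xyz <- function(dir) {
  for (nm in names(.xyz_texts)) {
    writeLines(.xyz_texts[[nm]], file.path(dir, paste0(nm, ".xyz")))
  }
}
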