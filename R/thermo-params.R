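# Nearest-neighbor thermodynamic parameter tables for DNA/DNA duplexes.
#
# Keys are "XY/ZW": top-strand dinucleotide 5'->3' over the bottom-strand
# dinucleotide 3'->5', so X pairs Z and Y pairs W. dH in kcal/mol, dS in
# cal/(mol K), 1 M NaCl reference state.
#
# Watson-Crick steps and initiation: unified oligonucleotide parameters
# (Allawi & SantaLucia 1997). Internal single mismatches: the
# Allawi/SantaLucia/Peyret series. Terminal mismatches: SantaLucia & Peyret.

.NN_WC <- list(
  "AA/TT" = c(-7.9, -22.2),
  "AT/TA" = c(-7.2, -20.4),
  "TA/AT" = c(-7.2, -21.3),
  "CA/GT" = c(-8.5, -22.7),
  "GT/CA" = c(-8.4, -22.4),
  "CT/GA" = c(-7.8, -21.0),
  "GA/CT" = c(-8.2, -22.2),
  "CG/GC" = c(-10.6, -27.2),
  "GC/CG" = c(-9.8, -24.4),
  "GG/CC" = c(-8.0, -19.9)
)

.NN_INIT       <- c(0, 0)      # general duplex initiation
.NN_INIT_AT    <- c(2.3, 4.1)  # per A/T terminal base pair
.NN_INIT_GC    <- c(0.1, -2.8) # per G/C terminal base pair
.NN_SYM        <- c(0, -1.4)   # self-complementary symmetry correction

.NN_IMM <- list(
  "AA/TA" = c(1.2, 1.7),   "AA/TC" = c(2.3, 4.6),   "AA/TG" = c(-0.6, -2.3),
  "AC/TA" = c(5.3, 14.6),  "AC/TC" = c(0.0, -4.4),  "AC/TT" = c(0.7, 0.2),
  "AG/TA" = c(-0.7, -2.3), "AG/TG" = c(-3.1, -9.5), "AG/TT" = c(1.0, 0.9),
  "AT/TC" = c(-1.2, -6.2), "AT/TG" = c(-2.5, -8.3), "AT/TT" = c(-2.7, -10.8),
  "CA/GA" = c(-0.9, -4.2), "CA/GC" = c(1.9, 3.7),   "CA/GG" = c(-0.7, -2.3),
  "CC/GA" = c(0.6, -0.6),  "CC/GC" = c(-1.5, -7.2), "CC/GT" = c(-0.8, -4.5),
  "CG/GA" = c(-4.0, -13.2),"CG/GG" = c(-4.9, -15.3),"CG/GT" = c(-4.1, -11.7),
  "CT/GC" = c(-1.5, -6.1), "CT/GG" = c(-2.8, -8.0), "CT/GT" = c(-5.0, -15.8),
  "GA/CA" = c(-2.9, -9.8), "GA/CC" = c(5.2, 14.2),  "GA/CG" = c(-0.6, -1.0),
  "GC/CA" = c(-0.7, -3.8), "GC/CC" = c(3.6, 8.9),   "GC/CT" = c(2.3, 5.4),
  "GG/CA" = c(0.5, 3.2),   "GG/CG" = c(-6.0, -15.8),"GG/CT" = c(3.3, 10.4),
  "GG/TT" = c(5.8, 16.3),
  "GT/CC" = c(5.2, 13.5),  "GT/CG" = c(-4.4, -12.3),"GT/CT" = c(-2.2, -8.4),
  "GT/TG" = c(4.1, 9.5),
  "TA/AA" = c(4.7, 12.9),  "TA/AC" = c(3.4, 8.0),   "TA/AG" = c(0.7, 0.7),
  "TC/AA" = c(7.6, 20.2),  "TC/AC" = c(6.1, 16.4),  "TC/AT" = c(1.2, 0.7),
  "TG/AA" = c(3.0, 7.4),   "TG/AG" = c(1.6, 3.6),   "TG/AT" = c(-0.1, -1.7),
  "TG/GT" = c(-1.4, -6.2),
  "TT/AC" = c(1.0, 0.7),   "TT/AG" = c(-1.3, -5.3), "TT/AT" = c(0.2, -1.5)
)

.NN_TMM <- list(
  "AA/TA" = c(-3.1, -7.8),  "AA/TC" = c(-1.6, -4.0),  "AA/TG" = c(-1.9, -4.4),
  "AC/TA" = c(-1.8, -3.8),  "AC/TC" = c(-0.1, 0.5),   "AC/TT" = c(-0.9, -1.7),
  "AG/TA" = c(-2.5, -5.9),  "AG/TG" = c(-1.1, -2.1),  "AG/TT" = c(-3.2, -8.7),
  "AT/TC" = c(-2.3, -6.3),  "AT/TG" = c(-3.5, -9.4),  "AT/TT" = c(-2.4, -6.5),
  "CA/GA" = c(-4.3, -10.7), "CA/GC" = c(-2.6, -5.9),  "CA/GG" = c(-3.9, -9.6),
  "CC/GA" = c(-2.7, -6.0),  "CC/GC" = c(-2.1, -5.1),  "CC/GT" = c(-3.2, -8.0),
  "CG/GA" = c(-6.0, -15.5), "CG/GG" = c(-3.8, -9.5),  "CG/GT" = c(-3.8, -9.0),
  "CT/GC" = c(-3.9, -10.6), "CT/GG" = c(-6.6, -18.7), "CT/GT" = c(-6.1, -16.9),
  "GA/CA" = c(-8.0, -22.5), "GA/CC" = c(-5.0, -13.8), "GA/CG" = c(-4.3, -11.1),
  "GC/CA" = c(-3.2, -7.1),  "GC/CC" = c(-3.9, -10.6), "GC/CT" = c(-4.9, -13.5),
  "GG/CA" = c(-4.6, -11.4), "GG/CG" = c(-0.7, -19.2), "GG/CT" = c(-5.7, -15.9),
  "GT/CC" = c(-3.0, -7.8),  "GT/CG" = c(-5.9, -16.1), "GT/CT" = c(-7.4, -21.2),
  "TA/AA" = c(-2.5, -6.3),  "TA/AC" = c(-2.3, -5.9),  "TA/AG" = c(-2.0, -4.7),
  "TC/AA" = c(-2.7, -7.0),  "TC/AC" = c(-0.7, -1.3),  "TC/AT" = c(-2.5, -6.3),
  "TG/AA" = c(-2.4, -5.8),  "TG/AG" = c(-1.1, -2.7),  "TG/AT" = c(-3.9, -10.5),
  "TT/AC" = c(-0.7, -1.2),  "TT/AG" = c(-3.6, -9.8),  "TT/AT" = c(-3.2, -8.9)
)

# A step key "XY/ZW" read from the other strand is "WZ/YX"; expand each table
# so both orientations resolve with a single lookup.
.expandKeys <- function(tab) {
  rev2 <- function(k) {
    s <- strsplit(k, "")[[1]]
    paste0(s[5], s[4], "/", s[2], s[1])
  }
  out <- tab
  for (k in names(tab)) {
    rk <- rev2(k)
    if (is.null(out[[rk]])) out[[rk]] <- tab[[k]]
  }
  out
}

.makeLookup <- function(tabs) {
  tab <- do.call(c, lapply(tabs, .expandKeys))
  dh <- vapply(tab, `[`, numeric(1), 1L)
  ds <- vapply(tab, `[`, numeric(1), 2L)
  list(dh = dh, ds = ds)
}

# Combined stack lookup: WC and internal-mismatch keys never collide (the
# implied base pairing differs), so one flat table serves the zipping pass.
.NN_STACK <- .makeLookup(list(.NN_WC, .NN_IMM))
.NN_TERM  <- .makeLookup(list(.NN_TMM))

.GAS_CONSTANT <- 1.987 # cal/(mol K)

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
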