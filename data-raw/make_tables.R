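# Generates the plain-text colorimetric tables under inst/extdata/.
# Run from the package root:  Rscript data-raw/make_tables.R
#
# Sources:
#  - CIE 1931 2-degree color-matching functions, 10 nm tabulation
#    (standard CIE table, 380-780 nm).
#  - CIE daylight components S0/S1/S2, 10 nm tabulation (standard CIE
#    table; here 380-780 nm, the range the package integrates over).
#  - Cone fundamentals: derived from the CMF table via the
#    Hunt-Pointer-Estevez transform (normalized to equal-energy white),
#    each channel rescaled to unit peak. Any externally tabulated
#    fundamentals (e.g., Stockman-Sharpe 2 deg from CVRL) can be supplied
#    at run time instead via cone_fundamentals(path = ...).

cmf <- matrix(byrow = TRUE, ncol = 4, c(
  380, 0.001368, 0.000039, 0.006450,
  390, 0.004243, 0.000120, 0.020050,
  400, 0.014310, 0.000396, 0.067850,
  410, 0.043510, 0.001210, 0.207400,
  420, 0.134380, 0.004000, 0.645600,
  430, 0.283900, 0.011600, 1.385600,
  440, 0.348280, 0.023000, 1.747060,
  450, 0.336200, 0.038000, 1.772110,
  460, 0.290800, 0.060000, 1.669200,
  470, 0.195360, 0.090980, 1.287640,
  480, 0.095640, 0.139020, 0.812950,
  490, 0.032010, 0.208020, 0.465180,
  500, 0.004900, 0.323000, 0.272000,
  510, 0.009300, 0.503000, 0.158200,
  520, 0.063270, 0.710000, 0.078250,
  530, 0.165500, 0.862000, 0.042160,
  540, 0.290400, 0.954000, 0.020300,
  550, 0.433450, 0.994950, 0.008750,
  560, 0.594500, 0.995000, 0.003900,
  570, 0.762100, 0.952000, 0.002100,
  580, 0.916300, 0.870000, 0.001650,
  590, 1.026300, 0.757000, 0.001100,
  600, 1.062200, 0.631000, 0.000800,
  610, 1.002600, 0.503000, 0.000340,
  620, 0.854450, 0.381000, 0.000190,
  630, 0.642400, 0.265000, 0.000050,
  640, 0.447900, 0.175000, 0.000020,
  650, 0.283500, 0.107000, 0.000000,
  660, 0.164900, 0.061000, 0.000000,
  670, 0.087400, 0.032000, 0.000000,
  680, 0.046770, 0.017000, 0.000000,
  690, 0.022700, 0.008210, 0.000000,
  700, 0.011359, 0.004102, 0.000000,
  710, 0.005790, 0.002091, 0.000000,
  720, 0.002899, 0.001047, 0.000000,
  730, 0.001440, 0.000520, 0.000000,
  740, 0.000690, 0.000249, 0.000000,
  750, 0.000332, 0.000120, 0.000000,
  760, 0.000166, 0.000060, 0.000000,
  770, 0.000083, 0.000030, 0.000000,
  780, 0.000042, 0.000015, 0.000000))
cmf <- as.data.frame(cmf)
names(cmf) <- c("wavelength_nm", "xbar", "ybar", "zbar")

day <- matrix(byrow = TRUE, ncol = 4, c(
  380,  63.40, 38.50,  3.00,
  390,  65.80, 35.00,  1.20,
  400,  94.80, 43.40, -1.10,
  410, 104.80, 46.30, -0.50,
  420, 105.90, 43.90, -0.70,
  430,  96.80, 37.10, -1.20,
  440, 113.90, 36.70, -2.60,
  450, 125.60, 35.90, -2.90,
  460, 125.50, 32.60, -2.80,
  470, 121.30, 27.90, -2.60,
  480, 121.30, 24.30, -2.60,
  490, 113.50, 20.10, -1.80,
  500, 113.10, 16.20, -1.50,
  510, 110.80, 13.20, -1.30,
  520, 106.50,  8.60, -1.20,
  530, 108.80,  6.10, -1.00,
  540, 105.30,  4.20, -0.50,
  550, 104.40,  1.90, -0.30,
  560, 100.00,  0.00,  0.00,
  570,  96.00, -1.60,  0.20,
  580,  95.10, -3.50,  0.50,
  590,  89.10, -3.50,  2.10,
  600,  90.50, -5.80,  3.20,
  610,  90.30, -7.20,  4.10,
  620,  88.40, -8.60,  4.70,
  630,  84.00, -9.50,  5.10,
  640,  85.10,-10.90,  6.70,
  650,  81.90,-10.70,  7.30,
  660,  82.60,-12.00,  8.60,
  670,  84.90,-14.00,  9.80,
  680,  81.30,-13.60, 10.20,
  690,  71.90,-12.00,  8.30,
  700,  74.30,-13.30,  9.60,
  710,  76.40,-12.90,  8.50,
  720,  63.30,-10.60,  7.00,
  730,  71.70,-11.60,  7.30,
  740,  77.00,-12.20,  8.60,
  750,  65.20,-10.20,  7.10,
  760,  47.70, -7.80,  5.10,
  770,  68.60,-11.20,  9.00,
  780,  65.00,-10.40,  7.80))
day <- as.data.frame(day)
names(day) <- c("wavelength_nm", "S0", "S1", "S2")

# Hunt-Pointer-Estevez cone responses from the 1931 CMFs.
hpe <- matrix(c(0.38971, 0.68898, -0.07868,
                -0.22981, 1.18340, 0.04641,
                0.00000, 0.00000, 1.00000),
              nrow = 3, byrow = TRUE)
lms <- as.matrix(cmf[, c("xbar", "ybar", "zbar")]) %*% t(hpe)
lms[lms < 0] <- 0
lms <- sweep(lms, 2, apply(lms, 2, max), "/")
cones <- data.frame(wavelength_nm = cmf$wavelength_nm,
                    sL = lms[, 1], sM = lms[, 2], sS = lms[, 3])

dir.create(file.path("inst", "extdata"), recursive = TRUE, showWarnings = FALSE)
write.csv(cmf, file.path("inst", "extdata", "cie1931_cmf_2deg_10nm.csv"),
          row.names = FALSE)
write.csv(day, file.path("inst", "extdata", "cie_daylight_components_10nm.csv"),
          row.names = FALSE)
write.csv(cones, file.path("inst", "extdata", "cone_fundamentals_2deg.csv"),
          row.names = FALSE)
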