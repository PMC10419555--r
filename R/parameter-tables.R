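## Published craniofacial reference statistics used to calibrate the
## synthetic cohort generator: per-class x per-sex means/SDs for the 14
## measured parameters, per-class head norms (H, L, W, V) and asymmetry
## summaries (AH, AF), and the roster composition.

#' Default cohort calibration tables
#'
#' Per-parameter normal calibration (mean, SD) for every occlusion class x
#' sex cell of the 14-parameter battery, per-class head norms (H, L, W in
#' mm, V in cm^3) and asymmetry levels (AH, AF in mm), and the default
#' roster sizes (class I: 38 M / 36 F; class II: 24 / 26; class III:
#' 4 / 11).
#'
#' @return nested list with elements \code{measurements} (parameter ->
#'   class -> sex -> c(mean, sd)), \code{head} (metric -> class ->
#'   c(mean, sd)) and \code{roster} (class -> sex -> n).
#' @export
referenceNorms <- function() {
  M <- function(...) {
    v <- c(...)
    list(I = list(M = v[1:2], F = v[3:4]),
         II = list(M = v[5:6], F = v[7:8]),
         III = list(M = v[9:10], F = v[11:12]))
  }
  measurements <- list(
    ## mid-face
    Sn_to_NPg = M(6.49, 1.84, 5.85, 1.96, 6.76, 1.76, 6.12, 2.02,
                  4.62, 1.50, 6.02, 3.40),
    N_Sto = M(63.53, 2.93, 62.45, 3.76, 64.71, 3.14, 61.96, 3.49,
              61.68, 4.41, 64.27, 7.05),
    N_Sn = M(43.22, 2.32, 43.53, 2.43, 43.99, 2.16, 42.26, 2.31,
             42.15, 2.32, 44.93, 5.49),
    Sn_Sto = M(20.54, 1.90, 19.15, 2.42, 21.00, 1.97, 20.02, 2.33,
               19.70, 2.26, 19.66, 2.46),
    nasolabial_angle = M(106.85, 10.50, 104.34, 12.48, 109.58, 9.47,
                         104.86, 10.73, 108.11, 13.77, 111.43, 10.59),
    ## lower face
    Sto_Gn = M(43.72, 3.72, 43.53, 4.21, 46.28, 4.87, 43.56, 4.72,
               45.63, 6.35, 43.01, 4.02),
    Go_Gn = M(61.45, 4.33, 60.00, 3.64, 60.84, 4.43, 60.26, 3.34,
              60.50, 6.03, 62.93, 2.87),
    Pg_to_NB = M(2.60, 2.22, 1.82, 1.54, 2.16, 3.29, 1.95, 1.41,
                 2.19, 1.24, 1.82, 1.64),
    labiomental_angle = M(140.48, 12.09, 143.97, 11.80, 135.18, 14.60,
                          139.31, 13.34, 143.79, 16.38, 141.69, 9.53),
    lowerlip_submental_angle = M(121.81, 8.31, 119.60, 9.51, 124.55, 9.19,
                                 119.50, 10.10, 120.89, 6.51, 116.56, 13.27),
    gonial_angle = M(146.85, 3.89, 146.65, 3.80, 145.38, 4.75,
                     146.38, 4.75, 144.51, 3.80, 147.92, 2.09),
    ## overall
    N_Gn = M(103.80, 4.31, 102.65, 5.58, 106.98, 4.75, 102.02, 5.56,
             104.16, 7.32, 104.59, 9.06),
    facial_convexity = M(163.55, 4.45, 164.84, 4.92, 163.04, 4.08,
                         163.91, 5.04, 167.98, 3.68, 165.29, 7.19),
    soft_tissue_convexity = M(137.57, 3.53, 136.96, 3.25, 135.91, 2.82,
                              136.21, 3.31, 140.65, 3.51, 136.74, 4.20)
  )
  H <- function(...) {
    v <- c(...)
    list(I = v[1:2], II = v[3:4], III = v[5:6])
  }
  head <- list(
    H  = H(228.60, 9.81, 228.82, 10.54, 227.10, 9.13),
    L  = H(181.38, 6.87, 182.19, 7.74, 180.58, 8.25),
    W  = H(160.98, 10.10, 164.77, 12.70, 161.00, 8.78),
    AH = H(2.32, 1.14, 2.18, 1.13, 1.85, 0.85),
    AF = H(0.94, 0.51, 0.88, 0.35, 0.82, 0.36),
    V  = H(3544.74, 325.32, 3611.73, 455.37, 3519.81, 352.09)
  )
  roster <- list(I = list(M = 38L, F = 36L),
                 II = list(M = 24L, F = 26L),
                 III = list(M = 4L, F = 11L))
  list(measurements = measurements, head = head, roster = roster)
}
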