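# Published per-gene RNAi strength averages for the common-target group,
# as printed (4 decimals, rounded half away from zero).
published_common_averages <- function() {
  c(
    "Blimp-1" = 2.1158,
    "Bx" = 5.7270,
    "CadN" = -2.1481,
    "CG10737" = 18.2600,
    "CG11206" = -3.7402,
    "CG12918" = -5.3436,
    "CG13606" = 1.6099,
    "CG3077" = 1.6012,
    "CG32105" = 2.5570,
    "CG33090" = 0.3904,
    "CG3376" = 0.1872,
    "CG3534" = -4.3640,
    "CG3624" = 3.1832,
    "CG4360" = 4.7780,
    "CG4984" = -2.9691,
    "CG5599" = 22.6593,
    "CG6129" = 14.1150,
    "CG7510" = 6.9305,
    "CG8121" = -0.7240,
    "CG8128" = -8.1508,
    "CG8303" = 11.0345,
    "CG8323" = 1.7840,
    "CG8360" = -2.4035,
    "CG8417" = -11.5805,
    "CG9376" = -10.0650,
    "CG9650" = 0.4336,
    "Cpr" = -15.5400,
    "Dysb" = 1.6958,
    "endoB" = -16.4445,
    "Ero1L" = 3.1058,
    "garz" = 45.3800,
    "Gfat2" = 0.9978,
    "Myd88" = 1.9035,
    "Nak" = 0.2233,
    "pdm2" = 1.0590,
    "porin" = -7.7000,
    "Ptp69D" = 1.4233,
    "RASSF8" = 0.8924,
    "raw" = 10.6350,
    "regucalcin" = 9.8860,
    "RhoGAP68F" = 1.5819,
    "Sbf" = -4.4590,
    "sens" = -3.6995,
    "Sirt2" = -4.8680,
    "SP555" = 9.7850,
    "T48" = 10.6500,
    "Thd1" = 0.3609,
    "Tm1" = 5.3700,
    "toe" = 13.0900,
    "up" = 3.9300,
    "Vha68-1" = 0.6250
  )
}
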