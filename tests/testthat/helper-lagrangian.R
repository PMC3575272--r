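# Independent Euler-Lagrange forward dynamics of the two-link stance
# model (symbolically derived, machine-generated code). Used as an
# oracle against the package's Kane/Newton-Euler implementation.
# state: internal 8-state (aS, hS, aC, hC, rates); platform accel in
# the INTERNAL frame (y left); par: named list of body parameters.
lagrangian_qdd <- function(state, tau, aplat_int, par) {
  th1 <- state[1]; th2 <- state[2]; th3 <- state[3]; th4 <- state[4]
  w1s <- state[5]; w2s <- state[6]; w3s <- state[7]; w4s <- state[8]
  axp <- aplat_int[1]; ayp <- aplat_int[2]
  m1 <- par$m1; m2 <- par$m2; L1 <- par$L1; d1 <- par$d1; d2 <- par$d2
  I1x <- par$I1[1]; I1y <- par$I1[2]; I1z <- par$I1[3]
  I2x <- par$I2[1]; I2y <- par$I2[2]; I2z <- par$I2[3]; g <- par$g
  x0 <- cos(th3)
  x1 <- x0^2
  x2 <- sin(th3)
  x3 <- x2^2
  x4 <- sin(th2)
  x5 <- x4^2
  x6 <- x3*x5
  x7 <- cos(th4)
  x8 <- x7^2
  x9 <- I2y*x8
  x10 <- sin(th4)
  x11 <- x10^2
  x12 <- I2z*x11
  x13 <- sin(th1)
  x14 <- x13^2
  x15 <- L1^2
  x16 <- m2*x15
  x17 <- x1*x16
  x18 <- cos(th1)
  x19 <- x18^2
  x20 <- d1^2
  x21 <- m1*x20
  x22 <- x1*x21
  x23 <- I2y*x10
  x24 <- cos(th2)
  x25 <- x0*x7
  x26 <- x2*x25
  x27 <- x24*x26
  x28 <- 2*x27
  x29 <- I2z*x10
  x30 <- I2y*x11
  x31 <- x24^2
  x32 <- x3*x31
  x33 <- I2z*x8
  x34 <- x0*x2
  x35 <- L1*m2
  x36 <- d2*x35
  x37 <- x34*x36
  x38 <- x14*x37
  x39 <- 2*x10
  x40 <- x38*x39
  x41 <- x19*x37
  x42 <- x39*x41
  x43 <- d2^2
  x44 <- m2*x43
  x45 <- x44*x8
  x46 <- x45*x5
  x47 <- x14*x46
  x48 <- x3*x44
  x49 <- x11*x48
  x50 <- x19*x46
  x51 <- x1*x14
  x52 <- x36*x7
  x53 <- 2*x24
  x54 <- x52*x53
  x55 <- x1*x19
  x56 <- x10*x24
  x57 <- x14*x56
  x58 <- 2*x26
  x59 <- x44*x58
  x60 <- x57*x59
  x61 <- x19*x56
  x62 <- x59*x61
  x63 <- x1*x45
  x64 <- x31*x63
  x65 <- x0*x9
  x66 <- x0*x12
  x67 <- x2*x24
  x68 <- x67*x7
  x69 <- x24*x25
  x70 <- x14*x36
  x71 <- x19*x36
  x72 <- x2*x7
  x73 <- x44*x72
  x74 <- x31*x45
  x75 <- x14*x74
  x76 <- x19*x74
  x77 <- x0*x47 + x0*x50 + x0*x75 + x0*x76 - x23*x68 + x29*x68 - x57*x73 - x61*x73 + x65 + x66 + x69*x70 + x69*x71
  x78 <- I2x*x2
  x79 <- x24*x78
  x80 <- x23*x25
  x81 <- x25*x29
  x82 <- x30*x67
  x83 <- x33*x67
  x84 <- x14*x2
  x85 <- x19*x2
  x86 <- x10*x44
  x87 <- x25*x86
  x88 <- x14*x87
  x89 <- x19*x87
  x90 <- x45*x67
  x91 <- x14*x90
  x92 <- x19*x90
  x93 <- x4*(x52*x84 + x52*x85 + x79 + x80 - x81 - x82 - x83 + x88 + x89 + x91 + x92)
  x94 <- x10*x36
  x95 <- x14*x94
  x96 <- x0*x19
  x97 <- x11*x44
  x98 <- x45*x84
  x99 <- x45*x85
  x100 <- x4*(-x0*x95 + x78 + x84*x97 + x85*x97 - x94*x96 + x98 + x99)
  x101 <- x5*x63
  x102 <- x10*x48
  x103 <- x51*x86
  x104 <- x55*x86
  x105 <- x14*x26
  x106 <- x24*x44
  x107 <- x19*x26
  x108 <- x4*x7
  x109 <- x108*(x102 + x103 + x104 + x105*x106 + x106*x107 + x23 - x27*x44 - x29 - x37 + x38 + x41)
  x110 <- x3*x56
  x111 <- x1*x57
  x112 <- x1*x61
  x113 <- x108*x44
  x114 <- x113*(x105 + x107 + x110 + x111 + x112 - x26 - x57 - x61)
  x115 <- x30*x5
  x116 <- x33*x5
  x117 <- x21*x3
  x118 <- x16*x3
  x119 <- x55*x97
  x120 <- x51*x97
  x121 <- x32*x45
  x122 <- x1*x7
  x123 <- x122*x36
  x124 <- x3*x52
  x125 <- x124*x19
  x126 <- x124*x14
  x127 <- x44*x56
  x128 <- -x127*x58 + x60 + x62
  x129 <- I2x*x24
  x130 <- x26*x86
  x131 <- x24*x49
  x132 <- x24*x63
  x133 <- x105*x86
  x134 <- x107*x86
  x135 <- x48*x8
  x136 <- x135*x14
  x137 <- x136*x24
  x138 <- x120*x24
  x139 <- x135*x19
  x140 <- x139*x24
  x141 <- x119*x24
  x142 <- x123 + x125 + x126 + x129 - x130*x31 - x130 + x131 + x132 + x133*x31 + x133 + x134*x31 + x134 + x137 + x138 + x140 + x141 - x37*x56 + x37*x57 + x37*x61
  x143 <- x5*x97
  x144 <- g*x13
  x145 <- d1*m1
  x146 <- w1s*w3s
  x147 <- 2*x146
  x148 <- x147*x34
  x149 <- w2s*w3s
  x150 <- x149*x2
  x151 <- axp*x13
  x152 <- d2*m2
  x153 <- x108*x152
  x154 <- x151*x153
  x155 <- axp*x18
  x156 <- g*x18
  x157 <- x153*x156
  x158 <- w2s*w4s
  x159 <- 2*x158
  x160 <- w3s^2
  x161 <- x158*x67
  x162 <- w4s*x4
  x163 <- w3s*x162
  x164 <- x163*x30
  x165 <- x163*x33
  x166 <- x144*x152
  x167 <- x146*x2
  x168 <- 2*x167
  x169 <- w1s*w4s
  x170 <- 2*x169
  x171 <- x122*x23
  x172 <- x160*x23
  x173 <- x108*x2
  x174 <- w2s^2
  x175 <- x150*x31
  x176 <- x30*x4
  x177 <- x160*x24
  x178 <- x176*x177
  x179 <- x33*x4
  x180 <- x177*x179
  x181 <- x147*x24
  x182 <- x169*x67
  x183 <- 2*x182
  x184 <- x29*x7
  x185 <- x108*x23
  x186 <- 2*w4s
  x187 <- w3s*x186
  x188 <- x108*x29
  x189 <- w1s*w2s
  x190 <- 2*x189
  x191 <- x148*x16
  x192 <- x148*x21
  x193 <- x189*x3*x53
  x194 <- x147*x94
  x195 <- x0*x174
  x196 <- x108*x70
  x197 <- x108*x36
  x198 <- x197*x96
  x199 <- w4s^2
  x200 <- x0*x199
  x201 <- x170*x36
  x202 <- x0*x36
  x203 <- x159*x57
  x204 <- x159*x61
  x205 <- x190*x197
  x206 <- 4*x146*x24*x36
  x207 <- x5*x7
  x208 <- x207*x86
  x209 <- x170*x208
  x210 <- x108*x86
  x211 <- x160*x210
  x212 <- 2*x150
  x213 <- x111*x44
  x214 <- x147*x7
  x215 <- x112*x44
  x216 <- w1s*x0
  x217 <- x186*x216
  x218 <- x159*x88
  x219 <- x159*x89
  x220 <- x113*x2
  x221 <- x187*x220
  x222 <- x132*x190*x4
  x223 <- x31*x7
  x224 <- x170*x223
  x225 <- x23*x7
  x226 <- x129*x4
  x227 <- w1s^2
  x228 <- x227*x3
  x229 <- x227*x34
  x230 <- x108*x229
  x231 <- x147*x68
  x232 <- x4*x45
  x233 <- x232*x24
  x234 <- x14*x227
  x235 <- x19*x227
  x236 <- x174*x232*x24
  x237 <- x199*x232*x24
  x238 <- x159*x223
  x239 <- x14*x86
  x240 <- x19*x86
  x241 <- x147*x25*x44
  x242 <- x147*x31
  x243 <- x170*x88
  x244 <- x170*x89
  x245 <- x160*x34
  x246 <- x210*x245
  x247 <- x199*x34
  x248 <- x210*x247
  x249 <- 2*x149
  x250 <- x249*x34
  x251 <- x159*x207
  x252 <- x187*x34
  x253 <- x113*x252
  x254 <- I2x*x162
  x255 <- ayp*x0
  x256 <- x2*x35
  x257 <- x145*x2
  x258 <- x5*x78
  x259 <- w2s*x162
  x260 <- x151*x152
  x261 <- x0*x10
  x262 <- ayp*x152
  x263 <- x25*x262
  x264 <- x152*x156
  x265 <- x174*x7
  x266 <- x265*x29
  x267 <- x162*x216
  x268 <- x0*x227
  x269 <- x160*x94
  x270 <- x199*x94
  x271 <- x187*x36
  x272 <- x189*x2*x31
  x273 <- x122*x227
  x274 <- x273*x29
  x275 <- x27*x36
  x276 <- x229*x31
  x277 <- 2*w1s*x162*x94
  x278 <- 2*x259
  x279 <- x122*x127
  x280 <- 2*x0
  x281 <- w3s*w4s
  x282 <- x249*x3
  x283 <- x110*x187
  x284 <- x229*x97
  x285 <- x245*x97
  x286 <- x247*x97
  x287 <- 2*x97
  x288 <- x267*x287
  x289 <- x149*x4
  x290 <- 2*x289
  x291 <- x122*x86
  x292 <- x110*x44*x7
  x293 <- x160*x292
  x294 <- x199*x292
  x295 <- x67*x97
  x296 <- x295*x96
  x297 <- x170*x220
  x298 <- x210*x250
  x299 <- x32*x86
  x300 <- x187*x7
  x301 <- x299*x300
  x302 <- x113*x34
  x303 <- I2x*x4
  x304 <- x0*x146
  x305 <- x10*x4
  x306 <- x189*x67
  x307 <- x146*x4
  x308 <- x0*x56
  x309 <- x160*x36
  x310 <- x227*x67
  x311 <- x147*x67
  x312 <- x252*x45
  x313 <- x227*x32
  x314 <- x227*x36
  x315 <- x194*x4
  x316 <- x0*x160
  x317 <- x295*x316
  x318 <- x200*x295
  x319 <- x187*x292
  x320 <- x159*x210*x34
  x321 <- x265*x86
  x322 <- x321*x5
  x323 <- x160*x7
  x324 <- x199*x208
  x325 <- x199*x7
  x326 <- x287*x304*x4
  x327 <- x259*x53
  x328 <- x14*x97
  x329 <- x19*x97
  x330 <- x252*x31
  x331 <- x102*x7
  x332 <- x102*x323
  x333 <- x102*x325
  x334 <- x190*x5
  x335 <- x190*x31
  x336 <- x113*x168
  x337 <- x268*x295
  x338 <- x227*x31*x7
  x339 <- x265*x31
  x340 <- x31*x323
  x341 <- x31*x325
  x342 <- x113*x250
  M11 <- I1y*x1 + I1z*x3 + I2x*x6 + x1*x12 + x1*x9 + x14*x17 + x14*x22 + x14*x49 + x14*x64 + x17*x19 + x19*x22 + x19*x49 + x19*x64 - x23*x28 + x28*x29 + x30*x32 + x32*x33 - x40 - x42 + x47 + x50 + x51*x54 + x54*x55 - x60 - x62
  M12 <- x77
  M13 <- x93
  M14 <- x100
  M21 <- x77
  M22 <- x101*x14 + x101*x19 + x12 + x45*x6 + x75 + x76 + x9
  M23 <- x109
  M24 <- x114
  M31 <- x93
  M32 <- x109
  M33 <- I1x + I2x*x31 + x115 + x116 + x117*x14 + x117*x19 + x118*x14 + x118*x19 + x119 + x120 + x121*x14 + x121*x19 + x123*x53 + x125*x53 + x126*x53 + x128 + x17 + x22 - x37*x39 + x40 + x42 + x49 + x64
  M34 <- x142
  M41 <- x100
  M42 <- x114
  M43 <- x142
  M44 <- I2x + x119*x31 + x120*x31 + x128 + x136 + x139 + x14*x143 + x143*x19 + x32*x97 + x63
  r1 <- -I1y*x148 + 2*I1z*w1s*w3s*x0*x2 + 2*I2x*w1s*w2s*x24*x3*x4 + 2*I2x*w1s*w3s*x0*x2*x5 + I2x*w2s*w3s*x2*x31 + I2x*w2s*w4s*x2*x24 + I2x*w3s*w4s*x0*x4 + I2x*x0*x160*x24*x4 + 2*I2y*w1s*w2s*x0*x10*x2*x4*x7 + 2*I2y*w1s*w3s*x0*x11*x2*x31 + 2*I2y*w1s*w3s*x10*x24*x3*x7 + 2*I2y*w1s*w4s*x0*x11*x2*x24 + 2*I2y*w1s*w4s*x10*x3*x31*x7 + I2y*w2s*w3s*x11*x2*x5 + I2y*w2s*w4s*x11*x2*x24 + I2y*w3s*w4s*x0*x4*x8 + I2y*x10*x174*x2*x4*x7 + 2*I2z*w1s*w3s*x0*x2*x31*x8 + 2*I2z*w1s*w3s*x1*x10*x24*x7 + 2*I2z*w1s*w4s*x0*x2*x24*x8 + 2*I2z*w1s*w4s*x1*x10*x7 + I2z*w2s*w3s*x2*x5*x8 + 2*I2z*w2s*w4s*x0*x10*x7 + I2z*w2s*w4s*x2*x24*x8 + I2z*w3s*w4s*x0*x11*x4 + 2*I2z*w3s*w4s*x10*x2*x24*x4*x7 + I2z*x10*x160*x2*x4*x7 + L1*axp*m2*x0*x18 + 2*L1*d2*m2*w1s*w3s*x10*x14*x3 + 2*L1*d2*m2*w1s*w3s*x10*x19*x3 + L1*d2*m2*x0*x14*x160*x4*x7 + L1*d2*m2*x0*x160*x19*x4*x7 + axp*d1*m1*x0*x18 + axp*d2*m2*x0*x18*x24*x7 + d2*g*m2*x10*x13*x2 + 2*m2*w1s*w2s*x0*x10*x14*x2*x4*x43*x7 + 2*m2*w1s*w2s*x0*x10*x19*x2*x4*x43*x7 + 2*m2*w1s*w2s*x14*x24*x4*x43*x8 + 2*m2*w1s*w2s*x19*x24*x4*x43*x8 + 2*m2*w1s*w3s*x0*x11*x14*x2*x43 + 2*m2*w1s*w3s*x0*x11*x19*x2*x43 + 2*m2*w1s*w3s*x10*x14*x24*x3*x43*x7 + 2*m2*w1s*w3s*x10*x19*x24*x3*x43*x7 + 2*m2*w1s*w4s*x0*x11*x14*x2*x24*x43 + 2*m2*w1s*w4s*x0*x11*x19*x2*x24*x43 + 2*m2*w1s*w4s*x10*x14*x3*x43*x7 + 2*m2*w1s*w4s*x10*x19*x3*x43*x7 + 2*m2*w2s*w4s*x11*x14*x2*x24*x43 + 2*m2*w2s*w4s*x11*x19*x2*x24*x43 + 2*m2*w3s*w4s*x0*x14*x4*x43*x8 + 2*m2*w3s*w4s*x0*x19*x4*x43*x8 + m2*x0*x14*x160*x24*x4*x43*x8 + m2*x0*x160*x19*x24*x4*x43*x8 + m2*x10*x14*x174*x2*x4*x43*x7 + m2*x10*x174*x19*x2*x4*x43*x7 - x0*x144*x145 - x0*x144*x35 - x0*x164 - x0*x165 - x0*x178 - x0*x180 - x10*x152*x155*x2 - x103*x224 - x104*x224 - x105*x201 - x105*x206 - x107*x201 - x107*x206 - x111*x201 - x112*x201 - x12*x150 - x12*x161 - x14*x191 - x14*x192 - x14*x209 - x14*x222 - x148*x75 - x148*x76 - x149*x5*x78 - x150*x9 - x154 - x157 - x159*x80 - x161*x9 - x166*x69 - x168*x65 - x168*x66 - x170*x171 - x170*x184*x32 - x171*x181 - x172*x173 - x173*x174*x29 - x174*x198 - x175*x30 - x175*x33 - x176*x193 - x179*x193 - x181*x184*x3 - x183*x65 - x183*x66 - x185*x187*x67 - x188*x190*x34 - x19*x191 - x19*x192 - x19*x209 - x19*x222 - x194*x51 - x194*x55 - x195*x196 - x196*x200 - x198*x199 - x202*x203 - x202*x204 - x205*x51 - x205*x55 - x211*x84 - x211*x85 - x212*x47 - x212*x50 - x213*x214 - x214*x215 - x217*x91 - x217*x92 - x218*x31 - x218*x5 - x219*x31 - x219*x5 - x221*x57 - x221*x61
  r2 <- I2x*w1s*w3s*x2*x5 + I2x*w3s*w4s*x4 + I2x*x160*x24*x4 + I2y*w1s*w3s*x11*x2*x31 + I2y*w1s*w4s*x11*x2*x24 + I2y*w3s*w4s*x4*x8 + I2y*x11*x227*x24*x3*x4 + 2*I2z*w1s*w3s*x0*x10*x24*x7 + I2z*w1s*w3s*x2*x31*x8 + 2*I2z*w1s*w4s*x0*x10*x7 + I2z*w1s*w4s*x2*x24*x8 + 2*I2z*w2s*w4s*x10*x7 + I2z*w3s*w4s*x11*x4 + I2z*x0*x10*x2*x227*x4*x7 + I2z*x227*x24*x3*x4*x8 + L1*d2*m2*x1*x14*x160*x4*x7 + L1*d2*m2*x1*x14*x227*x4*x7 + L1*d2*m2*x1*x160*x19*x4*x7 + L1*d2*m2*x1*x19*x227*x4*x7 + L1*d2*m2*x160*x3*x4*x7 + axp*d2*m2*x18*x24*x7 + ayp*d2*m2*x2*x4*x7 + 2*m2*w2s*w3s*x0*x2*x43*x5*x8 + 2*m2*w3s*w4s*x0*x10*x2*x24*x4*x43*x7 + 2*m2*w3s*w4s*x1*x14*x4*x43*x8 + 2*m2*w3s*w4s*x1*x19*x4*x43*x8 + 2*m2*w3s*w4s*x3*x4*x43*x8 + m2*x0*x10*x160*x2*x4*x43*x7 + m2*x0*x10*x199*x2*x4*x43*x7 + m2*x1*x14*x160*x24*x4*x43*x8 + m2*x1*x14*x174*x24*x4*x43*x8 + m2*x1*x14*x199*x24*x4*x43*x8 + m2*x1*x14*x227*x24*x4*x43*x8 + m2*x1*x160*x19*x24*x4*x43*x8 + m2*x1*x174*x19*x24*x4*x43*x8 + m2*x1*x19*x199*x24*x4*x43*x8 + m2*x1*x19*x227*x24*x4*x43*x8 + m2*x160*x24*x3*x4*x43*x8 + m2*x174*x24*x3*x4*x43*x8 + m2*x199*x24*x3*x4*x43*x8 - w1s*w4s*x79 - x0*x154 - x0*x157 - x103*x251 - x104*x251 - x115*x167 - x116*x167 - x12*x167 - x12*x182 - x14*x236 - x14*x237 - x14*x246 - x14*x248 - x146*x31*x78 - x159*x225 - x159*x6*x7*x86 - x164 - x165 - x166*x24*x7 - x167*x9 - x170*x80 - x170*x91 - x170*x92 - x178 - x180 - x181*x80 - x182*x9 - x19*x236 - x19*x237 - x19*x246 - x19*x248 - x226*x228 - x23*x230 - x230*x239 - x230*x240 - x231*x70 - x231*x71 - x233*x234 - x233*x235 - x238*x239 - x238*x240 - x241*x57 - x241*x61 - x242*x98 - x242*x99 - x243*x31 - x243*x5 - x244*x31 - x244*x5 - x250*x47 - x250*x50 - x253*x57 - x253*x61
  r3 <- I1y*x0*x2*x227 - I1z*x229 + I2x*w1s*w2s*x2*x31 + 2*I2y*w1s*w2s*x0*x10*x24*x7 + I2y*w1s*w2s*x11*x2*x5 + I2y*w1s*w2s*x2*x8 + I2y*w1s*w4s*x0*x4*x8 + 2*I2y*w2s*w3s*x11*x24*x4 + I2y*w2s*w4s*x4*x8 + 2*I2y*w3s*w4s*x10*x5*x7 + I2y*x0*x2*x227*x8 + I2y*x1*x10*x227*x24*x7 + I2y*x10*x174*x24*x7 + I2z*w1s*w2s*x11*x2 + I2z*w1s*w2s*x2*x5*x8 + I2z*w1s*w4s*x0*x11*x4 + 2*I2z*w1s*w4s*x10*x2*x24*x4*x7 + 2*I2z*w2s*w3s*x24*x4*x8 + I2z*w2s*w4s*x11*x4 + I2z*x0*x11*x2*x227 + I2z*x10*x227*x24*x3*x7 + 2*L1*d2*m2*w1s*w2s*x14*x2*x24*x7 + 2*L1*d2*m2*w1s*w2s*x19*x2*x24*x7 + 2*L1*d2*m2*w2s*w4s*x0*x10*x2*x4 + 2*L1*d2*m2*w3s*w4s*x0*x14*x2*x7 + 2*L1*d2*m2*w3s*w4s*x0*x19*x2*x7 + 2*L1*d2*m2*x0*x14*x160*x2*x24*x7 + L1*d2*m2*x0*x14*x174*x2*x24*x7 + L1*d2*m2*x0*x14*x199*x2*x24*x7 + 2*L1*d2*m2*x0*x14*x2*x227*x24*x7 + 2*L1*d2*m2*x0*x160*x19*x2*x24*x7 + L1*d2*m2*x0*x174*x19*x2*x24*x7 + L1*d2*m2*x0*x19*x199*x2*x24*x7 + 2*L1*d2*m2*x0*x19*x2*x227*x24*x7 + L1*d2*m2*x1*x10*x14*x160 + L1*d2*m2*x1*x10*x14*x227 + L1*d2*m2*x1*x10*x160*x19 + L1*d2*m2*x1*x10*x19*x227 + L1*d2*m2*x10*x160*x3 + ayp*d2*m2*x10*x2 + m1*x0*x14*x160*x2*x20 + m1*x0*x14*x2*x20*x227 + m1*x0*x160*x19*x2*x20 + m1*x0*x19*x2*x20*x227 + 2*m2*w1s*w2s*x0*x10*x14*x24*x43*x7 + 2*m2*w1s*w2s*x0*x10*x19*x24*x43*x7 + 2*m2*w1s*w2s*x14*x2*x31*x43*x8 + 2*m2*w1s*w2s*x19*x2*x31*x43*x8 + 2*m2*w2s*w3s*x0*x10*x2*x4*x43*x7 + 2*m2*w2s*w4s*x0*x10*x2*x24*x4*x43*x7 + 2*m2*w3s*w4s*x0*x11*x2*x24*x43 + 2*m2*w3s*w4s*x0*x14*x2*x24*x43*x8 + 2*m2*w3s*w4s*x0*x19*x2*x24*x43*x8 + 2*m2*w3s*w4s*x1*x10*x14*x43*x7 + 2*m2*w3s*w4s*x1*x10*x19*x43*x7 + 2*m2*w3s*w4s*x10*x3*x43*x7 + m2*x0*x11*x160*x2*x43 + m2*x0*x11*x199*x2*x43 + m2*x0*x14*x15*x160*x2 + m2*x0*x14*x15*x2*x227 + m2*x0*x14*x160*x2*x31*x43*x8 + m2*x0*x14*x174*x2*x31*x43*x8 + m2*x0*x14*x199*x2*x31*x43*x8 + m2*x0*x14*x2*x227*x31*x43*x8 + m2*x0*x15*x160*x19*x2 + m2*x0*x15*x19*x2*x227 + m2*x0*x160*x19*x2*x31*x43*x8 + m2*x0*x174*x19*x2*x31*x43*x8 + m2*x0*x19*x199*x2*x31*x43*x8 + m2*x0*x19*x2*x227*x31*x43*x8 + m2*x1*x10*x14*x160*x24*x43*x7 + m2*x1*x10*x14*x174*x24*x43*x7 + m2*x1*x10*x14*x199*x24*x43*x7 + m2*x1*x10*x14*x227*x24*x43*x7 + m2*x1*x10*x160*x19*x24*x43*x7 + m2*x1*x10*x174*x19*x24*x43*x7 + m2*x1*x10*x19*x199*x24*x43*x7 + m2*x1*x10*x19*x227*x24*x43*x7 + m2*x10*x160*x24*x3*x43*x7 + m2*x10*x174*x24*x3*x43*x7 + m2*x10*x199*x24*x3*x43*x7 - w2s*x254 - x1*x197*x249 - x1*x269 - x1*x270 - x1*x271*x56 - x108*x282*x71 - x119*x278 - x120*x278 - x132*x290 - x137*x290 - x14*x280*x281*x295 - x14*x284 - x14*x285 - x14*x286 - x14*x288 - x14*x293 - x14*x294 - x14*x298 - x14*x301 - x140*x290 - x145*x255 - 2*x149*x226 - x151*x256 - x151*x257 - x156*x256 - x156*x257 - x16*x245 - x160*x279 - x160*x3*x95 - x174*x275 - x174*x34*x74 - x177*x36*x58 - x183*x185 - x187*x207*x29 - x187*x291*x31 - x187*x296 - x189*x258 - x189*x53*x81 - x19*x228*x94 - x19*x269*x3 - x19*x270*x3 - x19*x284 - x19*x285 - x19*x286 - x19*x288 - x19*x293 - x19*x294 - x19*x298 - x19*x301 - x196*x282 - x199*x275 - x199*x279 - x199*x3*x95 - x203*x302 - x204*x302 - x21*x245 - x216*x254 - x225*x228*x24 - x228*x95 - x234*x292 - x235*x292 - x24*x263 - x24*x266 - x24*x274 - x245*x74 - x247*x74 - x255*x35 - x258*x268 - x259*x30 - x259*x33 - x259*x40 - x259*x42 - x26*x271 - x260*x261 - x260*x68 - x261*x264 - x264*x68 - x267*x30 - x267*x33 - x272*x30 - x272*x33 - x276*x30 - x276*x33 - x277*x84 - x277*x85 - x278*x49 - x280*x281*x90 - x283*x70 - x283*x71 - x297*x57 - x297*x61
  r4 <- x103*x338 + x103*x339 + x103*x340 + x103*x341 + x104*x338 + x104*x339 + x104*x340 + x104*x341 + x105*x309 + x105*x314 + x107*x309 + x107*x314 + x110*x309 + x111*x309 + x111*x314 + x112*x309 + x112*x314 + x113*x250*x56 - x12*x289 + x12*x306 - x131*x278 - x136*x290 - x138*x278 - x139*x290 + x14*x312 - x14*x317 - x14*x318 - x14*x319 - x14*x320 + x14*x322 + x14*x324 + x14*x326 - x14*x332 - x14*x333 - x14*x337 - x141*x278 + x149*x176 + x149*x179 - x149*x303 - x152*x155*x305 + x160*x207*x29 - x160*x291 - x160*x296 + x166*x305 - x172*x207 + x176*x304 + x179*x304 + x184*x313 + x185*x311 - x187*x279 - x188*x311 + x189*x79 - x189*x82 - x189*x83 + x19*x312 - x19*x319 - x19*x320 + x19*x322 + x19*x324 + x19*x326 - x19*x332 - x19*x333 - x19*x337 + x190*x80 - x190*x81 + x190*x91 + x190*x92 - x195*x90 + x195*x91 + x195*x92 - x199*x291 - x199*x296 + x2*x262*x56 - x200*x90 + x200*x91 + x200*x92 + x208*x234 + x208*x235 + x213*x300 + x215*x300 - x225*x313 + x23*x265 + x23*x273 - x234*x331 - x235*x331 - x26*x309 - x260*x308 - x260*x72 - x263 - x264*x308 - x264*x72 - x266 - x268*x82 - x268*x83 + x268*x91 + x268*x92 - x274 - x289*x9 - x290*x63 + x299*x323 + x299*x325 + x303*x304 + x306*x9 - x307*x65 - x307*x66 + x310*x65 + x310*x66 - x312 + x315*x84 + x315*x85 - x316*x90 + x316*x91 + x316*x92 + x317 + x318 + x319 + x32*x321 + x320 + x327*x328 + x327*x329 - x328*x330 - x329*x330 + x330*x97 + x334*x88 + x334*x89 + x335*x88 + x335*x89 + x336*x57 + x336*x61 - x342*x57 - x342*x61
  M <- matrix(c(M11, M21, M31, M41, M12, M22, M32, M42, M13, M23, M33, M43, M14, M24, M34, M44), 4, 4)
  rhs <- as.numeric(tau) - c(r1, r2, r3, r4)
  as.numeric(solve(M, rhs))
}
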