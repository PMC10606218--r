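G[ASP]G[LAVSTIM][LM][VI]AVGY[MIV]DPGNWAT[DEASG]x(30,100)[IVL]A[CT][DA][LV]AE[VIL][IVLA]Gx(5,30)[GAVCSL][TAS][LFYIVC][AVGILST][MLVI]x(50,125)[IVM][LVI]GAT[LVI]MPHN[LI][YF]L[HQ][SGA]x(5,40)[FMLT][LVATIC][VILA]N[SAGL][ASG]x(2,50)[ACS]G[QLM][SN][SA][TA][VLI]T[GAS]
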