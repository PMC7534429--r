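treatment,trait_row,trait_col,value
normal,diploid_growth,diploid_growth,6.72
normal,diploid_growth,sporulation,8.83
normal,diploid_growth,haploid_viability,55.01
normal,diploid_growth,haploid_growth,3.58
normal,sporulation,sporulation,16.10
normal,sporulation,haploid_viability,162.01
normal,sporulation,haploid_growth,4.45
normal,haploid_viability,haploid_viability,5160.00
normal,haploid_growth,haploid_growth,7.62
salt,diploid_growth,diploid_growth,2.63
salt,diploid_growth,sporulation,5.41
salt,diploid_growth,haploid_viability,6.86
salt,diploid_growth,haploid_growth,5.94
salt,sporulation,sporulation,37.90
salt,sporulation,haploid_viability,225.19
salt,sporulation,haploid_growth,-33.02
salt,haploid_viability,haploid_viability,5230.00
salt,haploid_viability,haploid_growth,-152.89
salt,haploid_growth,haploid_growth,59.40
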