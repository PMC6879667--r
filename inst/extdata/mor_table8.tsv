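# Individual SNP P-values for association of mu-opioid receptor (OPRM1)
# variants with pain sensitivity.
snp	pvalue
rs563649	0.0007
rs9322446	0.0941
rs2075572	0.2957
rs533586	0.7037
rs540825	0.8171
rs675026	0.8012
rs660756	0.5745
rs677830	0.9891
rs623956	0.8308
rs609148	0.8208
rs497332	0.3139
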