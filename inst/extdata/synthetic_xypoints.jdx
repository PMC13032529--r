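##TITLE=Synthetic XYPOINTS test spectrum (generated fixture)
##JCAMP-DX=4.24
##XUNITS=1/CM
##YUNITS=ABSORBANCE
##NPOINTS=4
##XYPOINTS=(XY..XY)
1000.0, 0.10; 1010.0, 0.40
1020.0, 0.90; 1030.0, 0.20
##END=
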