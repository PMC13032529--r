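##TITLE=Synthetic triglyceride ester C=O test spectrum (generated fixture)
##JCAMP-DX=4.24
##DATA TYPE=INFRARED SPECTRUM
##XUNITS=1/CM
##YUNITS=ABSORBANCE
##FIRSTX=1800
##LASTX=1610
##DELTAX=-10
##XFACTOR=1
##YFACTOR=0.01
##NPOINTS=20
##XYDATA=(X++(Y..Y))
1800 2 3 5 9 18
1750 40 95 40 18 9
1700 5 3 2 2 1
1650 1 1 1 1 1
##END=
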