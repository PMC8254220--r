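>Bmok_GH11 Blastobotrys mokoenaii secreted GH11 xylanase, predicted protein sequence
MKLSNAITAICAAAVLAAPLEEEEVAKRSVTPSSTGTNNGYYYSFWSDGGGDVTYTNGNG
GSYSVEWTNCGNFVGGKGWNPGAAREINFSGSFNPSGNGYLSVYGWTTNPLVEYYIVESY
GDYNPGTAGTFLGTVDSDGSTYDIYKAVRTNAPSIEGTATFDQYWSIRRNHRTSGTVNTG
NHFNAWAQHGLQLGTHNYQIVATEGYQSSGSSSITVS
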