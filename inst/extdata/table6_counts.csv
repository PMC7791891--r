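dataset,source,total_images,CD4T,CD4negT,mDC,pDC,Bcell
fresh-frozen-DS,manual,240,2688,1161,292,1025,NA
FFPE-DS,manual,160,4104,2041,483,517,NA
FFPE-SS,manual,342,3714,2846,768,847,2436
fresh-frozen-DS,automatic,673,8216,4047,2160,2243,NA
FFPE-DS,automatic,380,8351,5340,1186,1519,NA
FFPE-SS,automatic,1332,11126,14962,2573,2436,7506
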