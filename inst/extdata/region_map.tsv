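province	region
Beijing	north
Inner Mongolia	north
Shandong	north
Shanxi	north
Shaanxi	north
Henan	north
Hebei	north
Liaoning	north
Jilin	north
Heilongjiang	north
Shanghai	border
Jiangsu	border
Anhui	border
Hubei	border
Sichuan	border
Chongqing	border
Guangdong	south
Guangxi	south
Yunnan	south
Guizhou	south
Hunan	south
Fujian	south
Zhejiang	south
Jiangxi	south
Hainan	south
Taiwan	south
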