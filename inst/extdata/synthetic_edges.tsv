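P001	P002
P001	P003
P001	P006
P001	P007
P001	P008
P001	P009
P001	P013
P001	P014
P001	P016
P001	P021
P001	P024
P001	P030
P002	P003
P002	P004
P002	P005
P002	P020
P003	P004
P003	P005
P003	P006
P003	P011
P003	P012
P004	P007
P004	P008
P005	P009
P005	P010
P005	P025
P005	P029
P008	P012
P008	P017
P008	P019
P008	P027
P009	P010
P009	P023
P010	P011
P010	P013
P010	P018
P010	P022
P010	P023
P010	P027
P011	P014
P011	P018
P011	P026
P011	P028
P011	P030
P012	P017
P012	P022
P012	P026
P013	P015
P013	P019
P013	P021
P013	P029
P014	P015
P014	P016
P014	P024
P014	P025
P014	P028
P015	P020
P023	P024
P006	P024
P006	P029
P012	P029
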