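name	country	continent
Afghanistan	Afghanistan	Asia
Albania	Albania	Europe
Algeria	Algeria	Africa
Angola	Angola	Africa
Argentina	Argentina	South America
Armenia	Armenia	Asia
Australia	Australia	Oceania
Austria	Austria	Europe
Azerbaijan	Azerbaijan	Asia
Bahrain	Bahrain	Asia
Bangladesh	Bangladesh	Asia
Belarus	Belarus	Europe
Belgium	Belgium	Europe
Benin	Benin	Africa
Bolivia	Bolivia	South America
Bosnia and Herzegovina	Bosnia and Herzegovina	Europe
Botswana	Botswana	Africa
Brazil	Brazil	South America
Brasil	Brazil	South America
Bulgaria	Bulgaria	Europe
Burkina Faso	Burkina Faso	Africa
Cambodia	Cambodia	Asia
Cameroon	Cameroon	Africa
Canada	Canada	North America
Chile	Chile	South America
China	China	Asia
P.R. China	China	Asia
PR China	China	Asia
People's Republic of China	China	Asia
Hong Kong	China	Asia
Taiwan	Taiwan	Asia
Colombia	Colombia	South America
Costa Rica	Costa Rica	North America
Croatia	Croatia	Europe
Cuba	Cuba	North America
Cyprus	Cyprus	Europe
Czech Republic	Czech Republic	Europe
Czechia	Czech Republic	Europe
Czechoslovakia	Czech Republic	Europe
Democratic Republic of the Congo	Democratic Republic of the Congo	Africa
Denmark	Denmark	Europe
Ecuador	Ecuador	South America
Egypt	Egypt	Africa
El Salvador	El Salvador	North America
Estonia	Estonia	Europe
Ethiopia	Ethiopia	Africa
Finland	Finland	Europe
France	France	Europe
Gabon	Gabon	Africa
Gambia	Gambia	Africa
Georgia	Georgia	Asia
Germany	Germany	Europe
Ghana	Ghana	Africa
Greece	Greece	Europe
Guatemala	Guatemala	North America
Guinea	Guinea	Africa
Haiti	Haiti	North America
Honduras	Honduras	North America
Hungary	Hungary	Europe
Iceland	Iceland	Europe
India	India	Asia
Indonesia	Indonesia	Asia
Iran	Iran	Asia
Iraq	Iraq	Asia
Ireland	Ireland	Europe
Israel	Israel	Asia
Italy	Italy	Europe
Ivory Coast	Ivory Coast	Africa
Cote d'Ivoire	Ivory Coast	Africa
Jamaica	Jamaica	North America
Japan	Japan	Asia
Jordan	Jordan	Asia
Kazakhstan	Kazakhstan	Asia
Kenya	Kenya	Africa
Korea	South Korea	Asia
South Korea	South Korea	Asia
Republic of Korea	South Korea	Asia
Kuwait	Kuwait	Asia
Laos	Laos	Asia
Latvia	Latvia	Europe
Lebanon	Lebanon	Asia
Libya	Libya	Africa
Lithuania	Lithuania	Europe
Luxembourg	Luxembourg	Europe
Madagascar	Madagascar	Africa
Malawi	Malawi	Africa
Malaysia	Malaysia	Asia
Mali	Mali	Africa
Malta	Malta	Europe
Mexico	Mexico	North America
Moldova	Moldova	Europe
Mongolia	Mongolia	Asia
Morocco	Morocco	Africa
Mozambique	Mozambique	Africa
Myanmar	Myanmar	Asia
Namibia	Namibia	Africa
Nepal	Nepal	Asia
Netherlands	Netherlands	Europe
The Netherlands	Netherlands	Europe
New Zealand	New Zealand	Oceania
Nicaragua	Nicaragua	North America
Niger	Niger	Africa
Nigeria	Nigeria	Africa
North Macedonia	North Macedonia	Europe
Norway	Norway	Europe
Oman	Oman	Asia
Pakistan	Pakistan	Asia
Panama	Panama	North America
Papua New Guinea	Papua New Guinea	Oceania
Paraguay	Paraguay	South America
Peru	Peru	South America
Philippines	Philippines	Asia
Poland	Poland	Europe
Portugal	Portugal	Europe
Qatar	Qatar	Asia
Romania	Romania	Europe
Russia	Russia	Europe
Russian Federation	Russia	Europe
USSR	Russia	Europe
Soviet Union	Russia	Europe
Rwanda	Rwanda	Africa
Saudi Arabia	Saudi Arabia	Asia
Senegal	Senegal	Africa
Serbia	Serbia	Europe
Yugoslavia	Serbia	Europe
Sierra Leone	Sierra Leone	Africa
Singapore	Singapore	Asia
Slovakia	Slovakia	Europe
Slovenia	Slovenia	Europe
Somalia	Somalia	Africa
South Africa	South Africa	Africa
Spain	Spain	Europe
Sri Lanka	Sri Lanka	Asia
Sudan	Sudan	Africa
Sweden	Sweden	Europe
Switzerland	Switzerland	Europe
Syria	Syria	Asia
Tanzania	Tanzania	Africa
Thailand	Thailand	Asia
Togo	Togo	Africa
Trinidad and Tobago	Trinidad and Tobago	North America
Tunisia	Tunisia	Africa
Turkey	Turkey	Asia
Uganda	Uganda	Africa
Ukraine	Ukraine	Europe
United Arab Emirates	United Arab Emirates	Asia
UAE	United Arab Emirates	Asia
United Kingdom	United Kingdom	Europe
UK	United Kingdom	Europe
U.K.	United Kingdom	Europe
Great Britain	United Kingdom	Europe
England	United Kingdom	Europe
Scotland	United Kingdom	Europe
Wales	United Kingdom	Europe
Northern Ireland	United Kingdom	Europe
United States	United States	North America
United States of America	United States	North America
USA	United States	North America
U.S.A.	United States	North America
U.S.	United States	North America
Uruguay	Uruguay	South America
Uzbekistan	Uzbekistan	Asia
Venezuela	Venezuela	South America
Vietnam	Vietnam	Asia
Viet Nam	Vietnam	Asia
Yemen	Yemen	Asia
Zambia	Zambia	Africa
Zimbabwe	Zimbabwe	Africa
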